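test_that("pairwise Phi_ST behaves at the analytic extremes", {
  # two populations with identical haplotype composition -> Phi ~ 0, p ~ 1
  seqs <- c("ACGTACGT", "ACGAACGT", "ACGTACTT", "TCGTACGT")
  a0 <- alignment(rep(seqs, 4), sprintf("s%d", 1:16),
                  rep(c("P1", "P2"), each = 8))
  dm0 <- tn93_distance_matrix(a0, NULL)
  r0 <- pairwise_phi_st(dm0, c("P1", "P2"), n_perm = 199, seed = 1)
  expect_lt(abs(r0$phi_st), 0.2)
  expect_gt(r0$p, 0.3)
  # each population fixed for its own haplotype, within distances 0 -> Phi = 1
  a1 <- alignment(c(rep("AAAAAAAA", 4), rep("GGGGGGGG", 4)),
                  sprintf("s%d", 1:8), rep(c("P1", "P2"), each = 4))
  r1 <- pairwise_phi_st(raw_distance_matrix(a1),
                        c("P1", "P2"), n_perm = 99, seed = 1,
                        populations = a1$population)
  expect_equal(r1$phi_st, 1)
  expect_lte(r1$p, 0.08)   # only 2/70 label partitions reach Phi = 1
  expect_error(pairwise_phi_st(dm0, c("P1", "P2"), n_perm = 0), "n_perm")
  base <- "ACGTACGTACGTACGT"
  one <- alignment(c(base, sub("T$", "C", base), base),
                   sprintf("s%d", 1:3), c("P1", "P1", "P2"))
  expect_error(pairwise_phi_st(tn93_distance_matrix(one, NULL),
                               c("P1", "P2"), 9, 1), "size error")
})

test_that("permutation p-values are reproducible and order-invariant", {
  a <- two_deme_alignment(theta = 8, M = 2, T_split = 0.5, n = 8, seed = 5)
  dm <- tn93_distance_matrix(a)
  r1 <- pairwise_phi_st(dm, c("deme1", "deme2"), n_perm = 299, seed = 7)
  r2 <- pairwise_phi_st(dm, c("deme1", "deme2"), n_perm = 299, seed = 7)
  expect_identical(r1$p, r2$p)
  # permuting the record order leaves statistic and p unchanged
  set.seed(9)
  o <- sample(n_seq(a))
  a2 <- alignment(a$seq[o, , drop = FALSE], a$id[o], a$population[o])
  r3 <- pairwise_phi_st(tn93_distance_matrix(a2), c("deme1", "deme2"),
                        n_perm = 299, seed = 7)
  expect_equal(r3$phi_st, r1$phi_st, tolerance = 1e-12)
  expect_lt(abs(r3$p - r1$p), 0.06)
  expect_gte(r1$p, 1 / 300)
})

test_that("two-deme Phi_ST matches the island-model expectation", {
  # exact two-island expectation: (Tb - Tw)/Tb = 1/(1 + 2M), M = 2Nm
  set.seed(31)
  M <- 2
  phis <- replicate(120, {
    a <- simulate_sample(scenario("isolation_with_migration", theta = 20,
                                  M = M, T_split = 50, n = c(10, 10)))$alignment
    d2 <- raw_distance_matrix(a)^2
    phylodem:::amova2_components(d2, a$population)$phi_st
  })
  expect_equal(mean(phis), 1 / (1 + 2 * M), tolerance = 0.12)
})

test_that("hierarchical AMOVA decomposes variance exactly and detects structure", {
  # conservation on random fixtures
  set.seed(13)
  for (r in 1:20) {
    n <- sample(12:24, 1)
    d <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    pops <- paste0("p", sample(1:4, n, replace = TRUE))
    while (length(unique(pops)) < 4 || min(table(pops)) < 2)
      pops <- paste0("p", sample(1:4, n, replace = TRUE))
    grp <- c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g2")
    cc <- phylodem:::amova3_components(d^2, pops, unname(grp[pops]))
    expect_equal(unname(sum(cc$ss[1:3])), unname(cc$ss["total"]),
                 tolerance = 1e-9)
  }
  # four populations drawn from one panmictic pool -> Phi_CT ~ 0, Phi_SC ~ 0
  pan <- simulate_sample(scenario("constant", theta = 10, n = 24),
                         seed = 19)$alignment
  a <- alignment(pan$seq, pan$id, rep(c("p1", "p2", "p3", "p4"), each = 6))
  am0 <- hierarchical_amova(tn93_distance_matrix(a),
                            c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g2"),
                            n_perm = 99, seed = 2)
  # point estimates are noisy at this size; the permutation tests must
  # not reject
  expect_gt(am0$p_ct, 0.1)
  expect_gt(am0$p_sc, 0.1)
  expect_gt(am0$p_st, 0.05)
  # between-group divergence only -> Phi_CT > 0, Phi_SC ~ 0
  sim <- simulate_sample(scenario("isolation_with_migration", theta = 15,
                                  M = 0, T_split = 4, n = c(12, 12)),
                         seed = 8)
  b <- sim$alignment
  pops <- ifelse(b$population == "deme1",
                 rep(c("p1", "p2"), length.out = n_seq(b)),
                 rep(c("p3", "p4"), length.out = n_seq(b)))
  pops[b$population == "deme1"] <- rep(c("p1", "p2"), 6)
  pops[b$population == "deme2"] <- rep(c("p3", "p4"), 6)
  b2 <- alignment(b$seq, b$id, pops)
  am1 <- hierarchical_amova(tn93_distance_matrix(b2),
                            c(p1 = "gA", p2 = "gA", p3 = "gB", p4 = "gB"),
                            n_perm = 99, seed = 3)
  expect_gt(am1$phi_ct, 0.2)
  expect_lt(abs(am1$phi_sc), 0.2)
  expect_error(hierarchical_amova(tn93_distance_matrix(b2),
                                  c(p1 = "g", p2 = "g", p3 = "g", p4 = "g")),
               "hierarchy")
})

test_that("one population per group reduces AMOVA Phi_ST to pairwise Phi_ST", {
  a <- two_deme_alignment(theta = 10, M = 1, T_split = 1, n = 8, seed = 3)
  dm <- tn93_distance_matrix(a)
  pw <- pairwise_phi_st(dm, c("deme1", "deme2"), n_perm = 9, seed = 1)
  am <- hierarchical_amova(dm, c(deme1 = "g1", deme2 = "g2"),
                           n_perm = 9, seed = 1)
  expect_equal(am$phi_st, pw$phi_st, tolerance = 1e-12)
})

test_that("temporal pooling merges null replicates and flags planted outliers", {
  set.seed(17)
  # two replicates drawn from one panmictic deme -> pooled
  sim <- simulate_sample(scenario("sudden_expansion", tau = 10, theta0 = 1,
                                  theta1 = 200, n = 30), seed = 4)
  a <- sim$alignment
  a <- alignment(a$seq, a$id, rep(c("R1", "R2"), each = 15),
                 rep(c(2003L, 2004L), each = 15))
  plan <- pool_temporal_samples(tn93_distance_matrix(a), c("R1", "R2"),
                                n_perm = 199, seed = 6)
  expect_setequal(plan$pooled, c("R1", "R2"))
  expect_length(plan$separate, 0)
  # single replicate is returned unchanged
  p1 <- pool_temporal_samples(tn93_distance_matrix(a), "R1")
  expect_identical(p1$pooled, "R1")
  # study-like fixture: the designed odd replicate is flagged
  ds <- make_study_like_dataset(seed = 23)
  dms <- tn93_distance_matrix(ds$alignment)
  plan2 <- pool_temporal_samples(dms, c("SIN03", "SIN04", "SIN08"),
                                 n_perm = 199, seed = 6)
  expect_true("SIN04" %in% plan2$separate)
  expect_setequal(plan2$pooled, c("SIN03", "SIN08"))
})

test_that("Slatkin linearisation and UPGMA recover planted clades", {
  phi <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  phi["a", "b"] <- phi["b", "a"] <- 0.01
  phi["c", "d"] <- phi["d", "c"] <- 0.01
  phi[c("a", "b"), c("c", "d")] <- 0.2
  phi[c("c", "d"), c("a", "b")] <- 0.2
  u <- slatkin_upgma(phi)
  expect_equal(u$D["a", "b"], 0.01 / 0.99, tolerance = 1e-12)
  # the two clades are monophyletic in the UPGMA tree
  tr <- u$tree
  expect_true(ape::is.monophyletic(tr, c("a", "b")))
  expect_true(ape::is.monophyletic(tr, c("c", "d")))
  # Phi = 0.5 -> D = 1; Phi = 1 -> error; negative clamped with warning
  phi2 <- phi; phi2["a", "b"] <- phi2["b", "a"] <- 0.5
  expect_equal(slatkin_upgma(phi2)$D["a", "b"], 1)
  phi3 <- phi; phi3["a", "b"] <- phi3["b", "a"] <- 1
  expect_error(slatkin_upgma(phi3), "infinite")
  phi4 <- phi; phi4["a", "b"] <- phi4["b", "a"] <- -0.02
  expect_warning(u4 <- slatkin_upgma(phi4), "clamped")
  expect_equal(u4$D["a", "b"], 0)
})

test_that("Mantel IBD: perfect linearity, exclusions, and the degenerate case", {
  k <- 5
  pops <- paste0("p", 1:k)
  geo <- abs(outer(1:k, 1:k, "-")) * 100
  dimnames(geo) <- list(pops, pops)
  # build Phi so that M = (1-Phi)/(2Phi) is exactly linear in distance
  Mtrue <- 1 + geo / 50
  phi <- 1 / (2 * Mtrue + 1)
  diag(phi) <- 0
  r <- mantel_ibd(phi, geo, n_perm = 999, seed = 3)
  expect_equal(r$r2, 1, tolerance = 1e-10)
  expect_lt(r$p, 0.05)
  # non-positive Phi pairs are flagged and excluded
  phi2 <- phi; phi2[1, 2] <- phi2[2, 1] <- -0.01
  expect_warning(r2 <- mantel_ibd(phi2, geo, n_perm = 99, seed = 3),
                 "excluded")
  expect_equal(nrow(r2$excluded_pairs), 1L)
  # excluding a population drops it from the test
  r3 <- mantel_ibd(phi, geo, n_perm = 99, seed = 3, exclude = "p1")
  expect_equal(r3$n_pops, 4L)
  # 3 populations: degenerate null warned
  expect_warning(mantel_ibd(phi[1:3, 1:3], geo[1:3, 1:3], n_perm = 19,
                            seed = 1), "degenerate")
})

test_that("Mantel permutation p agrees with vegan on a clean case", {
  skip_if_not_installed("vegan")
  set.seed(8)
  k <- 6
  pops <- paste0("p", 1:k)
  phi <- matrix(runif(k * k, 0.05, 0.4), k)
  phi <- (phi + t(phi)) / 2; diag(phi) <- 0
  dimnames(phi) <- list(pops, pops)
  geo <- as.matrix(dist(cbind(runif(k) * 500, runif(k) * 500)))
  dimnames(geo) <- list(pops, pops)
  ours <- mantel_ibd(phi, geo, n_perm = 4999, seed = 2)
  M <- (1 - phi) / (2 * phi); diag(M) <- 0
  vg <- vegan::mantel(as.dist(M), as.dist(geo), permutations = 4999)
  expect_equal(ours$r, vg$statistic, tolerance = 1e-10)
  # one-sided vs two-sided conventions differ; compare loosely
  expect_lt(abs(ours$p - 2 * min(vg$signif, 1 - vg$signif)), 0.15)
})

test_that("Bonferroni threshold matches the 15-test convention", {
  b <- bonferroni(runif(15), alpha = 0.05)
  expect_equal(b$threshold, 0.05 / 15)
  expect_false(bonferroni(c(0.0034, runif(14, 0.5, 1)))$significant[1])
  expect_true(bonferroni(c(0.0009, runif(14, 0.5, 1)))$significant[1])
  expect_equal(bonferroni(0.04)$threshold, 0.05)
  expect_error(bonferroni(numeric(0)), "empty")
})

test_that("Mantel p-values are calibrated under a random-distance null", {
  set.seed(27)
  k <- 6
  pops <- paste0("p", 1:k)
  phi <- matrix(runif(k * k, 0.05, 0.4), k)
  phi <- (phi + t(phi)) / 2; diag(phi) <- 0
  dimnames(phi) <- list(pops, pops)
  ps <- replicate(200, {
    geo <- as.matrix(dist(cbind(runif(k), runif(k)))) * 300
    dimnames(geo) <- list(pops, pops)
    mantel_ibd(phi, geo, n_perm = 99, seed = sample.int(1e6, 1))$p
  })
  # approximately uniform: mean near 1/2, mass spread across the range
  expect_equal(mean(ps), 0.5, tolerance = 0.12)
  expect_gt(mean(ps < 0.25), 0.12)
  expect_gt(mean(ps > 0.75), 0.12)
})
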