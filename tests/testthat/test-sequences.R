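test_that("alignment construction validates lengths, labels and alphabet", {
  a <- toy_alignment()
  expect_s3_class(a, "phd_alignment")
  expect_equal(n_seq(a), 4L)
  expect_equal(n_sites(a), 10L)
  expect_error(alignment(c("ACGT", "ACG"), c("a", "b"), "P"),
               "ragged")
  expect_error(alignment(c("ACXT"), "a", "P"), "alphabet")
  expect_error(alignment(c("ACGT", "ACGT"), c("a", "a"), "P"),
               "duplicated")
  expect_error(alignment(c("ACGT"), "a", ""), "population")
  expect_error(alignment(character(0), character(0), character(0)),
               "empty")
})

test_that("FASTA + labels round-trip is loss-free, including simulated data", {
  sim <- simulate_sample(scenario("constant", theta = 5, n = 12), seed = 42)
  fa <- tempfile(fileext = ".fa"); lb <- tempfile(fileext = ".tsv")
  write_alignment(sim$alignment, fa, lb)
  back <- read_alignment(fa, lb)
  expect_identical(back$seq, sim$alignment$seq)
  expect_identical(back$population, sim$alignment$population)
  expect_identical(back$year, sim$alignment$year)
  # missing label -> labelling error
  labs <- read.delim(lb)
  expect_error(read_alignment(fa, labs[-1L, ]), "labelling error")
  # ragged input -> alignment error
  writeLines(c(">a", "ACGTACGT", ">b", "ACGTACG"), fa)
  expect_error(read_alignment(fa, data.frame(id = c("a", "b"),
                                             population = "P", year = 1L)),
               "ragged")
})

test_that("haplotype collapsing matches the printed spectra and handles N wildcards", {
  # 5 copies of one sequence
  a <- alignment(rep("ACGT", 5), sprintf("s%d", 1:5), "P")
  h <- collapse_haplotypes(a)
  expect_equal(h$nh, 1L)
  expect_equal(unname(h$counts), 5L)
  # 43 sequences with exactly one duplicated haplotype: n=43, nh=42
  set.seed(1)
  seqs <- vapply(1:42, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""),
    character(1))
  seqs <- c(seqs, seqs[1])
  a43 <- alignment(seqs, sprintf("s%d", 1:43), "SIN")
  h43 <- collapse_haplotypes(a43)
  expect_equal(h43$n, 43L)
  expect_equal(h43$nh, 42L)
  expect_equal(sort(unname(h43$counts)), c(rep(1L, 41), 2L))
  # N matches any base by default but not in exact mode
  aN <- alignment(c("ACGT", "ACNT", "AGGT"), c("a", "b", "c"), "P")
  expect_equal(collapse_haplotypes(aN)$nh, 2L)
  expect_equal(collapse_haplotypes(aN, exact = TRUE)$nh, 3L)
  expect_error(collapse_haplotypes(a, populations = "missing"), "scope")
})

test_that("haplotype collapsing is idempotent and order-invariant", {
  for (s in 1:5) {
    sim <- simulate_sample(scenario("sudden_expansion", tau = 3, theta0 = 0,
                                    theta1 = 40, n = 15), seed = s)
    a <- sim$alignment
    h1 <- collapse_haplotypes(a)
    o <- sample(n_seq(a))
    a2 <- alignment(a$seq[o, , drop = FALSE], a$id[o], a$population[o],
                    a$year[o])
    h2 <- collapse_haplotypes(a2)
    expect_equal(h1$nh, h2$nh)
    expect_equal(sort(unname(h1$counts)), sort(unname(h2$counts)))
    # same membership up to haplotype relabelling
    canon <- function(h) sort(unname(vapply(lapply(h$membership, sort),
                                            paste, character(1),
                                            collapse = ",")))
    expect_equal(canon(h1), canon(h2))
  }
})

test_that("site classification follows the singleton / informative definitions", {
  cols <- cbind(c("A", "A", "A", "G", "G"),   # two states twice each
                c("A", "A", "A", "C", "A"),   # minor state once
                c("A", "A", "G", "G", "G"))   # informative transition
  a <- alignment(cols, sprintf("s%d", 1:5), "P")
  cs <- classify_sites(a)
  expect_equal(cs$sites$category, c("parsimony_informative", "singleton",
                                    "parsimony_informative"))
  expect_equal(cs$sites$type, c("transition", "transversion", "transition"))
  expect_equal(cs$summary$S,
               cs$summary$singleton + cs$summary$parsimony_informative)
  # (A,C,A,C,T): two states >=2 plus a singleton state, mixed types
  am <- alignment(c("A", "C", "A", "C", "T"), sprintf("s%d", 1:5), "P")
  cm <- classify_sites(am)
  expect_equal(cm$sites$category, "parsimony_informative")
  expect_equal(cm$sites$type, "both")
  # property: identity holds on simulated alignments
  for (s in 1:3) {
    sim <- simulate_sample(scenario("constant", theta = 8, n = 12), seed = s)
    sm <- classify_sites(sim$alignment)$summary
    expect_equal(sm$S, sm$singleton + sm$parsimony_informative)
  }
  expect_error(classify_sites(alignment("ACGT", "a", "P")), ">= 2")
})

test_that("doublet detection reports co-segregating adjacent changes only", {
  base <- strsplit("ACGTACGTACGTACGTACGT", "")[[1]]
  m <- matrix(rep(base, 8), nrow = 8, byrow = TRUE)
  # AT-like swap at positions 10-11 carried by the same 3 sequences
  m[1:3, 10] <- "T"; m[1:3, 11] <- "A"
  # independent variants at adjacent sites 15-16 in disjoint sequences
  m[1, 15] <- "T"; m[5, 16] <- "C"
  a <- alignment(m, sprintf("s%d", 1:8), "P")
  dd <- detect_doublets(a)
  expect_equal(nrow(dd), 1L)
  expect_equal(dd$pos1, 10L)
  expect_equal(dd$pos2, 11L)
  expect_equal(dd$n_carriers, 3L)
  # invariant alignment -> empty
  inv <- alignment(rep("ACGT", 4), sprintf("s%d", 1:4), "P")
  expect_equal(nrow(detect_doublets(inv)), 0L)
  # simulator hotspots produce detectable doublets
  scd <- scenario("constant", theta = 5, n = 12,
                  doublet_hotspots = c(10L, 200L), doublet_rate = 40)
  sd_ <- simulate_sample(scd, seed = 9)
  hits <- detect_doublets(sd_$alignment)
  expect_true(all(c(10L, 200L) %in% hits$pos1))
})
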