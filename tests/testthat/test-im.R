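test_that("HKY pruning likelihood matches phangorn on a fixed 4-taxon tree", {
  skip_if_not_installed("phangorn")
  sim <- simulate_sample(scenario("constant", theta = 4, n = 4), seed = 31)
  a <- sim$alignment
  tr <- ape::read.tree(text = "((s001:0.02,s002:0.05):0.01,(s003:0.03,s004:0.07):0.04);")
  pi <- unname(base_freqs(a))
  kappa <- 4
  # our kernel needs edges in postorder (children before parents)
  po <- ape::postorder(tr)
  ec <- tr$edge[po, 2]; ep <- tr$edge[po, 1]
  el <- tr$edge.length[po]
  # ape tips are numbered in tip.label order; align our rows to that
  rows <- match(tr$tip.label, a$id)
  codes <- phylodem:::code_bases(a$seq)
  ours <- phylodem:::.hky_loglik_cpp(ec, ep, el, codes[rows, , drop = FALSE],
                                     rep(1, ncol(codes)), pi, kappa)
  pd <- phangorn::phyDat(a$seq[rows, , drop = FALSE])
  # phangorn Q order: AC, AG, AT, CG, CT, GT
  fit <- phangorn::pml(tr, pd, bf = pi, Q = c(1, kappa, 1, 1, kappa, 1))
  expect_equal(ours, fit$logLik, tolerance = 1e-6)
})

test_that("im_config validates its settings", {
  expect_error(im_config(chain_length = 100, burn_in = 100), "config error")
  expect_error(im_config(M_max = 0), "positive")
  cfg <- im_config(chain_length = 2000, burn_in = 200)
  expect_s3_class(cfg, "phd_imconfig")
})

test_that("identical seed and config give identical chains", {
  a <- two_deme_alignment(theta = 15, M = 1, T_split = 1, n = 5, seed = 2)
  cfg <- im_config(chain_length = 3000, burn_in = 500, seed = 12)
  r1 <- run_im_mcmc(a, c("deme1", "deme2"), cfg)
  r2 <- run_im_mcmc(a, c("deme1", "deme2"), cfg)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$modes, r2$modes)
})

test_that("with a constant likelihood the marginals recover the uniform priors", {
  a <- two_deme_alignment(theta = 15, M = 1, T_split = 1, n = 6, seed = 2)
  cfg <- im_config(chain_length = 60000, burn_in = 5000, seed = 9,
                   likelihood_off = TRUE, thin = 10, grid_bins = 10)
  r <- run_im_mcmc(a, c("deme1", "deme2"), cfg)
  for (v in c("theta", "M", "T")) {
    mx <- r$priors[[paste0(v, "_max")]]
    expect_equal(mean(r$samples[, v]), mx / 2, tolerance = 0.12)
    # chi-square-style check on the 10-bin histogram
    dens <- r$grids[[v]]$density
    expect_lt(max(abs(dens - 0.1)), 0.05)
  }
})

test_that("the structured-coalescent prior density integrates bookkeeping correctly", {
  # panmictic limit: with T ~ 0 and no migrations the density reduces to
  # the Kingman product of exponentials
  set.seed(33)
  tipdeme <- rep(c(1L, 2L), each = 3L)
  st <- phylodem:::im_init_state(tipdeme, M = 0, T = 1e-9)
  lp <- phylodem:::im_logprior(st, M = 5, T = 1e-9)
  times <- sort(st$ttime[st$ttime > 0])
  k <- length(tipdeme):2
  waits <- diff(c(0, times))
  expect_equal(lp, -sum(choose(k, 2) * waits), tolerance = 1e-6)
  # migration events above T make the state invalid
  st2 <- st
  st2$migs[[1]] <- 0.5   # above T
  expect_identical(phylodem:::im_logprior(st2, M = 5, T = 1e-9), -Inf)
})

test_that("label swap leaves the posterior unchanged up to Monte Carlo error", {
  a <- two_deme_alignment(theta = 20, M = 1, T_split = 1.5, n = 8, seed = 6)
  cfg <- im_config(chain_length = 30000, burn_in = 5000, seed = 3)
  r12 <- run_im_mcmc(a, c("deme1", "deme2"), cfg)
  r21 <- run_im_mcmc(a, c("deme2", "deme1"), cfg)
  for (v in c("theta", "M", "T")) {
    spread <- sd(r12$samples[, v])
    expect_lt(abs(mean(r12$samples[, v]) - mean(r21$samples[, v])),
              max(0.75 * spread, 0.15 * r12$priors[[paste0(v, "_max")]]))
  }
})

test_that("panmictic data push migration mass away from zero", {
  # a single deme labelled as two: high migration explains the mixing
  sim <- simulate_sample(scenario("constant", theta = 20, n = 12), seed = 44)
  a <- sim$alignment
  a <- alignment(a$seq, a$id, rep(c("A", "B"), 6))
  dm <- tn93_distance_matrix(a)
  phi <- pairwise_phi_st(dm, c("A", "B"), n_perm = 199, seed = 1)
  expect_lt(abs(phi$phi_st), 0.15)
  cfg <- im_config(chain_length = 40000, burn_in = 8000, seed = 5)
  r <- run_im_mcmc(a, c("A", "B"), cfg)
  expect_gt(mean(r$samples[, "M"]), 0.1 * r$priors$M_max)
})

test_that("the summary table flags recent isolation when TMRCA < T", {
  fake <- function(pair, tmrca_years, Tmode, theta) {
    structure(list(pair = pair, modes = c(theta = theta, M = 1, T = Tmode),
                   tmrca = list(mean_years = tmrca_years),
                   priors = list()), class = "phd_im")
  }
  rm_ <- rate_model()
  # T years = Tmode * N(theta) * gen; choose values so TMRCA << T
  tab <- im_summary_table(list(fake(c("A", "B"), 1e4, 2, 50)), rm_)
  expect_true(tab$recent_isolation[1])
  tab2 <- im_summary_table(list(fake(c("A", "B"), 1e7, 0.01, 50)), rm_)
  expect_false(tab2$recent_isolation[1])
  expect_error(im_summary_table(list()), "empty")
})
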