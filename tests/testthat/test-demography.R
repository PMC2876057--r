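test_that("mismatch histogram matches combinatorial enumeration", {
  # monomorphic n = 5: all 10 pairs in class 0
  mono <- alignment(rep("ACGTACGT", 5), sprintf("s%d", 1:5), "P")
  h0 <- mismatch_histogram(mono)
  expect_equal(unname(h0$counts), 10L)
  expect_equal(names(h0$counts), "0")
  # two haplotypes differing at d = 3 sites with counts (a, b) = (4, 3)
  hap1 <- "AAAAAAAAAA"; hap2 <- "CCCAAAAAAA"
  a <- alignment(c(rep(hap1, 4), rep(hap2, 3)), sprintf("s%d", 1:7), "P")
  h <- mismatch_histogram(a)
  expect_equal(unname(h$counts[["3"]]), 4L * 3L)
  expect_equal(unname(h$counts[["0"]]), choose(4, 2) + choose(3, 2))
  expect_equal(sum(h$counts), choose(7, 2))
  expect_error(mismatch_histogram(alignment(c("AC", "AC"), c("a", "b"), "P")),
               "size error")
  # invariant: counts always sum to n(n-1)/2
  sim <- simulate_sample(scenario("constant", theta = 6, n = 13), seed = 3)
  expect_equal(sum(mismatch_histogram(sim$alignment)$counts), choose(13, 2))
})

test_that("expected mismatch curves are proper distributions with correct limits", {
  sup <- 0:3000
  for (p in list(c(10, 1, 500), c(0.5, 3, 3.5), c(25, 0, 99999)))
    expect_equal(sum(mismatch_expected_demographic(sup, p[1], p[2], p[3])),
                 1, tolerance = 1e-6)
  for (p in list(c(9, 3, 50), c(5, 2, 0), c(12, 1, 99999)))
    expect_equal(sum(mismatch_expected_spatial(sup, p[1], p[2], p[3])),
                 1, tolerance = 1e-6)
  # tau = 0 reduces to the equilibrium geometric for both models
  i <- 0:60
  geom <- 5^i / 6^(i + 1)
  expect_equal(mismatch_expected_demographic(i, 0, 5, 5), geom,
               tolerance = 1e-10)
  expect_equal(mismatch_expected_spatial(i, 0, 5, 2), geom,
               tolerance = 1e-10)
  # theta0 = 0, theta1 -> cap approaches a pure Poisson crest at tau
  pois <- dpois(i, 8)
  expect_equal(mismatch_expected_demographic(i, 8, 0, 99999), pois,
               tolerance = 1e-3)
  # strong migration makes the spatial model collapse to the demographic one
  sp <- mismatch_expected_spatial(i, 10, 2, 1e4)
  dd <- mismatch_expected_demographic(i, 10, 2, 99999)
  expect_lt(max(abs(sp - dd)), 1e-3)
})

test_that("fitters recover parameters exactly from noise-free expected curves", {
  ex <- mismatch_expected_demographic(0:40, 10, 1, 500)
  f <- fit_demographic_expansion(curve_histogram(ex), n = 50, n_boot = 0)
  expect_equal(f$tau, 10, tolerance = 0.05)
  expect_equal(f$theta0, 1, tolerance = 0.1)
  expect_lt(f$ssd, 1e-6)
  ex2 <- mismatch_expected_spatial(0:40, 9, 3, 50)
  f2 <- fit_spatial_expansion(curve_histogram(ex2), n = 50, n_boot = 0)
  expect_equal(f2$tau, 9, tolerance = 0.05)
  expect_equal(f2$theta, 3, tolerance = 0.1)
  expect_lt(f2$ssd, 1e-6)
  # no-expansion degenerate input: fitted curve approaches the geometric,
  # tau is unidentifiable and the fit is near-perfect regardless
  exg <- mismatch_expected_demographic(0:40, 0, 5, 5)
  fg <- fit_demographic_expansion(curve_histogram(exg), n = 50, n_boot = 0)
  expect_lt(fg$ssd, 1e-5)
  # spatial tau ~ 0 when the generator had no expansion
  fs <- fit_spatial_expansion(curve_histogram(exg), n = 50, n_boot = 0)
  expect_lt(fs$ssd, 1e-5)
})

test_that("bootstrap p and CI behave under matched simulation", {
  sim <- simulate_sample(scenario("sudden_expansion", tau = 10, theta0 = 1,
                                  theta1 = 500, n = 40), seed = 13)
  h <- mismatch_histogram(sim$alignment)
  f <- fit_demographic_expansion(h, n_boot = 100, seed = 5)
  expect_true(f$ci_tau[1] < f$ci_tau[2])
  expect_gte(f$p_ssd, 0)
  expect_lte(f$p_ssd, 1)
  # unimodal expansion histograms crest near tau on average
  expect_equal(as.integer(names(which.max(h$counts))), 10, tolerance = 4)
})

test_that("clock conversions are linear and reproduce the printed table values", {
  rm_ <- rate_model()
  expect_equal(rm_$u, 648 * 3.6e-8 * 2, tolerance = 1e-12)
  expect_equal(round(tau_to_time(13.4, rm_)$ky, 1), 287.2)
  expect_equal(round(tau_to_time(11.5, rm_)$ky, 1), 246.5)
  expect_equal(signif(theta_to_N(255.3, rm_), 2), 2.7e6)
  expect_equal(round(theta_to_N(5.1, rm_), -3), 55000)
  expect_equal(tau_to_time(0)$ky, 0)
  expect_equal(theta_to_N(0), 0)
  # linearity in the first argument
  expect_equal(tau_to_time(26.8, rm_)$years, 2 * tau_to_time(13.4, rm_)$years)
  # with the per-year rate fixed, u = L r g: doubling the generation
  # time halves the generation count and leaves calendar years unchanged
  rm2 <- rate_model(generation_years = 4)
  expect_equal(tau_to_time(10, rm2)$generations,
               10 / (2 * 648 * 3.6e-8 * 4))
  expect_equal(tau_to_time(10, rm2)$years, tau_to_time(10, rm_)$years)
  expect_equal(tau_to_time(10, rm2)$generations,
               tau_to_time(10, rm_)$generations / 2)
  expect_error(rate_model(rate_per_site_per_year = 0), "rate error")
  expect_error(tau_to_time(-1), ">= 0")
})

test_that("census arithmetic from catch statistics", {
  expect_equal(census_from_catch(10000, 450), 22.2e6, tolerance = 0.01)
  expect_equal(census_from_catch(450, 450), 1e6)
  expect_equal(census_from_catch(1, 500), 2000)
  expect_error(census_from_catch(0, 450), "positive")
})

test_that("Ewens haplotype-count distribution matches the CRP oracle", {
  for (n in c(5, 8, 12)) for (th in c(0.3, 1, 4, 20)) {
    expect_equal(ewens_k_distribution(n, th), crp_k_distribution(n, th),
                 tolerance = 1e-12)
  }
  # theta = 0: all mass on a single haplotype
  expect_equal(ewens_k_distribution(6, 0), c(1, rep(0, 5)))
})

test_that("Fu's Fs equals its definition and flags degenerate samples", {
  # n = 5, theta-hat = 1, nh = 2: direct Ewens evaluation
  pk <- crp_k_distribution(5, 1)
  s_prime <- sum(pk[2:5])
  fs_expected <- log(s_prime / (1 - s_prime))
  r <- phylodem:::fs_from_k_nh(1, 2, 5)
  expect_equal(r$fs, fs_expected, tolerance = 1e-12)
  # monomorphic sample is flagged, not an error
  mono <- alignment(rep("ACGTACGTAC", 6), sprintf("s%d", 1:6), "P")
  fm <- fu_fs(mono, n_sim = 0)
  expect_true(is.infinite(fm$fs))
  expect_match(fm$flag, "degenerate")
  expect_error(fu_fs(alignment(c("AC", "AC", "AC"), letters[1:3], "P")),
               "n >= 4")
})

test_that("Fs separates expansion from stationarity and its p-value is one-sided", {
  set.seed(41)
  fe <- replicate(8, fu_fs(expansion_alignment(n = 25, seed = sample.int(1e6, 1)),
                           n_sim = 0)$fs)
  fc <- replicate(8, {
    a <- simulate_sample(scenario("constant", theta = 10, n = 25))$alignment
    fu_fs(a, n_sim = 0)$fs
  })
  expect_lt(mean(fe), -8)
  expect_gt(mean(fc), -5)
  r <- fu_fs(expansion_alignment(n = 25, seed = 99), n_sim = 300, seed = 2)
  expect_lt(r$fs, -5)
  expect_lt(r$p, 0.05)
})
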