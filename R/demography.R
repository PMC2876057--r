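#' Mismatch distribution of a population sample
#'
#' Histogram of raw pairwise nucleotide differences (pairwise deletion)
#' over all sequence pairs, binned at integers from 0 upward.
#'
#' @param aln a `phd_alignment`
#' @param population population label (NULL = whole alignment)
#' @return object of class `phd_mismatch`: `counts` (named integer
#'   vector for classes 0..max), `n_pairs`, `n`
#' @export
mismatch_histogram <- function(aln, population = NULL) {
  if (!is.null(population)) aln <- subset_populations(aln, population)
  n <- n_seq(aln)
  if (n < 3L) stopf("size error: need n >= 3, got %d", n)
  nd <- raw_distance_matrix(aln)
  d <- nd[upper.tri(nd)]
  mx <- max(d)
  counts <- tabulate(d + 1L, nbins = mx + 1L)
  structure(list(counts = setNames(counts, 0:mx),
                 n_pairs = length(d), n = n),
            class = "phd_mismatch")
}

#' @export
print.phd_mismatch <- function(x, ...) {
  cat(sprintf("phd_mismatch: n = %d, %d pairs, classes 0..%d, mean %.3f\n",
              x$n, x$n_pairs, length(x$counts) - 1L,
              sum(as.numeric(names(x$counts)) * x$counts) / x$n_pairs))
  invisible(x)
}

## ---- expected mismatch curves --------------------------------------------
## Both models are computed from the coalescence-time density of a pair
## of genes measured in mutational time units (tau = 2uT), with the
## number of differences Poisson(t) given coalescence at t. The
## integrals have incomplete-gamma closed forms, evaluated in log space
## for stability at extreme theta.

## integral_0^tau a e^{-c t} e^{-t} t^i / i! dt  (log), c = total event rate - 1
log_int_lower <- function(i, a, c, tau) {
  log(a) - (i + 1) * log1p(c) +
    pgamma((1 + c) * tau, i + 1, log.p = TRUE)
}

#' Expected mismatch distribution under sudden demographic expansion
#'
#' The classic stationary-then-instantaneous-growth model: a population
#' at equilibrium theta0 grew to theta1 at mutational time tau before
#' present. Probabilities for difference classes `i`.
#'
#' @param i integer vector of difference classes (>= 0)
#' @param tau mutational time of the expansion (tau = 2uT)
#' @param theta0,theta1 scaled sizes before/after expansion
#' @return numeric vector of probabilities
#' @export
mismatch_expected_demographic <- function(i, tau, theta0, theta1) {
  if (tau < 0 || theta0 < 0 || theta1 <= 0)
    stopf("need tau >= 0, theta0 >= 0, theta1 > 0")
  a1 <- 1 / theta1
  lt1 <- if (tau > 0) log_int_lower(i, a1, a1, tau) else rep(-Inf, length(i))
  if (theta0 == 0) {
    lt2 <- -a1 * tau + dpois_log(i, tau)
  } else {
    a0 <- 1 / theta0
    lt2 <- -a1 * tau + log(a0) + a0 * tau - (i + 1) * log1p(a0) +
      pgamma((1 + a0) * tau, i + 1, lower.tail = FALSE, log.p = TRUE)
  }
  exp(lt1) + exp(lt2)
}

dpois_log <- function(i, lambda) {
  if (lambda == 0) return(ifelse(i == 0, 0, -Inf))
  i * log(lambda) - lambda - lgamma(i + 1)
}

#' Expected mismatch distribution under spatial (range) expansion
#'
#' Infinite-island range-expansion model: at mutational time tau a
#' single deme (size theta) expanded into infinitely many demes of size
#' theta exchanging migrants at scaled rate M = 2Nm. Both genes are
#' sampled from one deme. Lineages in the structured phase either
#' coalesce within the deme or separate by migration (and then cannot
#' meet again until the ancestral phase).
#'
#' @param i integer vector of difference classes
#' @param tau mutational time of the expansion
#' @param theta scaled deme size (= theta0 = theta1)
#' @param M scaled migration rate 2Nm
#' @return numeric vector of probabilities
#' @export
mismatch_expected_spatial <- function(i, tau, theta, M) {
  if (tau < 0 || theta <= 0 || M < 0)
    stopf("need tau >= 0, theta > 0, M >= 0")
  a <- 1 / theta; b <- M / theta
  lt1 <- if (tau > 0) log_int_lower(i, a, a + b, tau) else rep(-Inf, length(i))
  p_u <- exp(-(a + b) * tau) + (b / (a + b)) * (1 - exp(-(a + b) * tau))
  lt2 <- log(p_u) + log(a) + a * tau - (i + 1) * log1p(a) +
    pgamma((1 + a) * tau, i + 1, lower.tail = FALSE, log.p = TRUE)
  exp(lt1) + exp(lt2)
}

## ---- least-squares fitting ------------------------------------------------

PARAM_CAP <- 99999

mismatch_ssd <- function(obs_freq, expected) sum((obs_freq - expected)^2)

fit_mismatch_curve <- function(hist, curve_fun, starts, lower, upper) {
  classes <- 0:(length(hist$counts) - 1L)
  obs <- hist$counts / hist$n_pairs
  obj <- function(par) {
    e <- curve_fun(classes, par)
    if (any(!is.finite(e))) return(1e6)
    mismatch_ssd(obs, e)
  }
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    fit <- tryCatch(
      optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit))   # box constraints via clamping inside the objective
      fit <- tryCatch(
        optim(s, function(p) obj(pmin(pmax(p, lower), upper)),
              method = "Nelder-Mead", control = list(maxit = 500)),
        error = function(e) NULL)
    if (is.null(fit)) fit <- list(par = s, value = obj(s))
    fit$par <- pmin(pmax(fit$par, lower), upper)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best
}

#' Fit the sudden demographic expansion model to a mismatch histogram
#'
#' Least squares on mismatch frequencies over the observed difference
#' classes: parameters tau, theta0, theta1 (theta1 capped at 99999;
#' hitting the cap is flagged as a boundary, not an error). The SSD
#' goodness-of-fit p-value and the 95% CI of tau come from a parametric
#' bootstrap: coalescent samples are simulated under the fitted
#' expansion, refitted, and compared.
#'
#' @param hist a `phd_mismatch`
#' @param n sample size that produced the histogram (defaults to the
#'   histogram's own n)
#' @param n_boot parametric bootstrap replicates (0 skips the bootstrap)
#' @param seed integer RNG seed
#' @param L unused; retained so callers can pass alignment length
#' @param rm optional [rate_model()] to convert tau and its CI to years
#' @return object of class `phd_demfit`: tau, theta0, theta1, SSD,
#'   p_ssd, ci_tau, boundary flag, and `time` (from `rm`)
#' @export
fit_demographic_expansion <- function(hist, n = hist$n, n_boot = 1000,
                                      seed = 1, L = 648, rm = NULL) {
  mx <- length(hist$counts) - 1L
  kbar <- sum(0:mx * hist$counts) / hist$n_pairs
  mode_c <- which.max(hist$counts) - 1L
  starts <- list(c(max(mode_c, 0.5), 0.5, 10 * kbar + 5),
                 c(max(kbar, 0.5), 1, 500),
                 c(kbar / 2 + 0.1, kbar / 2, kbar * 2 + 1),
                 c(0.1, kbar, kbar + 1))
  lower <- c(0, 0, 0.01); upper <- c(4 * mx + 4, PARAM_CAP, PARAM_CAP)
  curve <- function(cl, par)
    mismatch_expected_demographic(cl, par[1], min(par[2], par[3]),
                                  max(par[3], 1e-6))
  best <- fit_mismatch_curve(hist, curve, starts, lower, upper)
  par <- best$par
  theta0 <- min(par[2], par[3]); theta1 <- max(par[3], theta0)
  out <- list(tau = par[1], theta0 = theta0, theta1 = theta1,
              ssd = best$value, model = "sudden_expansion",
              boundary = theta1 >= 0.995 * PARAM_CAP ||
                theta0 >= 0.995 * PARAM_CAP)
  if (n_boot > 0) {
    set.seed(seed)
    th1 <- max(theta1, 0.05)
    bstarts <- starts[1:2]
    boot <- replicate(n_boot, {
      gen <- sim_genealogy_sizechange(n, t_change = out$tau / th1,
                                      rel_size = theta0 / th1)
      h <- sim_mismatch_hist_gen(gen, th1)
      b <- fit_mismatch_curve(h, curve, bstarts, lower, upper)
      # SSD of this bootstrap sample against its own refitted curve
      c(ssd = b$value, tau = b$par[1])
    })
    out$p_ssd <- mean(boot["ssd", ] >= out$ssd)
    out$ci_tau <- unname(quantile(boot["tau", ], c(0.025, 0.975)))
    out$n_boot <- n_boot
  }
  if (!is.null(rm)) {
    out$time <- tau_to_time(out$tau, rm)
    if (!is.null(out$ci_tau))
      out$ci_time_ky <- vapply(out$ci_tau,
                               function(t) tau_to_time(t, rm)$ky, numeric(1))
    out$N0 <- theta_to_N(out$theta0, rm)
    out$N1 <- theta_to_N(out$theta1, rm)
  }
  structure(out, class = "phd_demfit")
}

#' @export
print.phd_demfit <- function(x, ...) {
  pars <- if (x$model == "sudden_expansion")
    sprintf("theta0 = %.2f, theta1 = %.1f", x$theta0, x$theta1)
  else sprintf("theta = %.2f, M = %.1f", x$theta, x$M)
  cat(sprintf("%s fit: tau = %.2f, %s, SSD = %.5f%s\n",
              x$model, x$tau, pars, x$ssd,
              if (isTRUE(x$boundary)) " [parameter at cap]" else ""))
  if (!is.null(x$p_ssd))
    cat(sprintf("  bootstrap: p(SSD) = %.3f, tau 95%% CI [%.2f, %.2f] (%d reps)\n",
                x$p_ssd, x$ci_tau[1], x$ci_tau[2], x$n_boot))
  if (!is.null(x$time))
    cat(sprintf("  expansion time: %.1f ky%s\n", x$time$ky,
                if (!is.null(x$ci_time_ky))
                  sprintf(" (CI %.1f-%.1f)", x$ci_time_ky[1], x$ci_time_ky[2])
                else ""))
  invisible(x)
}

#' Fit the spatial (range) expansion model to a mismatch histogram
#'
#' Least squares for the infinite-island range-expansion expected
#' mismatch: parameters tau, theta (= theta0 = theta1) and M = 2Nm
#' (capped at 99999). Bootstrap p-value and tau CI as in
#' [fit_demographic_expansion()], simulating under the finite-island
#' approximation of the model.
#'
#' @inheritParams fit_demographic_expansion
#' @return object of class `phd_demfit` with fields tau, theta, M, m
#'   (when `rm` given), ssd, p_ssd, ci_tau
#' @export
fit_spatial_expansion <- function(hist, n = hist$n, n_boot = 1000,
                                  seed = 1, L = 648, rm = NULL) {
  mx <- length(hist$counts) - 1L
  kbar <- sum(0:mx * hist$counts) / hist$n_pairs
  mode_c <- which.max(hist$counts) - 1L
  starts <- list(c(max(mode_c, 0.5), 1, 1),
                 c(max(kbar, 0.5), 0.5, 50),
                 c(kbar / 2 + 0.1, kbar, 5),
                 c(0.1, kbar, 500))
  lower <- c(0, 0.001, 0); upper <- c(4 * mx + 4, PARAM_CAP, PARAM_CAP)
  curve <- function(cl, par) mismatch_expected_spatial(cl, par[1], par[2], par[3])
  best <- fit_mismatch_curve(hist, curve, starts, lower, upper)
  par <- best$par
  out <- list(tau = par[1], theta = par[2], M = par[3], ssd = best$value,
              model = "spatial_expansion",
              boundary = par[3] >= 0.995 * PARAM_CAP)
  if (n_boot > 0) {
    set.seed(seed)
    bstarts <- starts[1:2]
    boot <- replicate(n_boot, {
      gen <- sim_genealogy_structured(rep(1L, n), out$M,
                                      t_merge = out$tau / out$theta,
                                      nd = 100L)
      h <- sim_mismatch_hist_gen(gen, out$theta)
      b <- fit_mismatch_curve(h, curve, bstarts, lower, upper)
      c(ssd = b$value, tau = b$par[1])
    })
    out$p_ssd <- mean(boot["ssd", ] >= out$ssd)
    out$ci_tau <- unname(quantile(boot["tau", ], c(0.025, 0.975)))
    out$n_boot <- n_boot
  }
  if (!is.null(rm)) {
    out$time <- tau_to_time(out$tau, rm)
    if (!is.null(out$ci_tau))
      out$ci_time_ky <- vapply(out$ci_tau,
                               function(t) tau_to_time(t, rm)$ky, numeric(1))
    out$N <- theta_to_N(out$theta, rm)
    out$m <- out$M * rm$u / out$theta
  }
  structure(out, class = "phd_demfit")
}

## ---- molecular-clock unit conversions ------------------------------------

#' Molecular-clock rate model
#'
#' Holds the per-site per-year mutation rate, the sequence length and
#' the generation time, and derives u, the per-sequence per-generation
#' mutation rate used by the mutational-time identities tau = 2uT and
#' theta = 2Nu.
#'
#' @param rate_per_site_per_year substitution rate per site per year
#'   (default 3.6e-8, i.e. 3.6% per Myr)
#' @param L sequence length (sites)
#' @param generation_years generation time in years
#' @return object of class `phd_ratemodel` with derived `u`
#' @export
rate_model <- function(rate_per_site_per_year = 3.6e-8, L = 648,
                       generation_years = 2) {
  if (rate_per_site_per_year <= 0 || L <= 0 || generation_years <= 0)
    stopf("rate error: all rate-model fields must be positive")
  structure(list(rate_per_site_per_year = rate_per_site_per_year, L = L,
                 generation_years = generation_years,
                 u = L * rate_per_site_per_year * generation_years),
            class = "phd_ratemodel")
}

#' @export
print.phd_ratemodel <- function(x, ...) {
  cat(sprintf("rate model: %.3g /site/year, L = %d, generation %.3g yr -> u = %.4g /sequence/generation\n",
              x$rate_per_site_per_year, x$L, x$generation_years, x$u))
  invisible(x)
}

#' Convert mutational expansion time tau to real time
#'
#' tau = 2uT with u per sequence per generation, so T = tau / (2u)
#' generations.
#'
#' @param tau mutational time (>= 0)
#' @param rm a [rate_model()]
#' @return list with `generations`, `years`, `ky`
#' @export
tau_to_time <- function(tau, rm = rate_model()) {
  if (tau < 0) stopf("tau must be >= 0")
  gens <- tau / (2 * rm$u)
  years <- gens * rm$generation_years
  list(generations = gens, years = years, ky = years / 1000)
}

#' Convert theta to an effective female count
#'
#' theta = 2Nu (haploid, maternally inherited), so N = theta / (2u).
#'
#' @param theta scaled population size (>= 0)
#' @param rm a [rate_model()]
#' @return effective number of females
#' @export
theta_to_N <- function(theta, rm = rate_model()) {
  if (any(theta < 0)) stopf("theta must be >= 0")
  theta / (2 * rm$u)
}

#' Harvested individuals implied by a catch weight
#'
#' @param catch_tonnes total catch in metric tons
#' @param mean_weight_g mean individual weight in grams
#' @return number of individuals
#' @export
census_from_catch <- function(catch_tonnes, mean_weight_g) {
  if (catch_tonnes <= 0 || mean_weight_g <= 0) stopf("inputs must be positive")
  catch_tonnes * 1e6 / mean_weight_g
}
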