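## Fu's Fs neutrality test: the probability, under the Ewens sampling
## distribution with theta estimated by the mean pairwise difference, of
## observing at least as many haplotypes as seen. Strongly negative Fs
## indicates an excess of rare haplotypes, the footprint of expansion.

#' Log unsigned Stirling numbers of the first kind, row n
#'
#' Returns log |s(n, k)| for k = 1..n via the standard recurrence,
#' carried in log space so any practical n is representable.
#' @param n positive integer
#' @return numeric vector of length n (log scale)
#' @keywords internal
log_stirling1_row <- function(n) {
  row <- 0            # n = 1: |s(1,1)| = 1
  if (n == 1L) return(row)
  for (m in 2:n) {
    prev <- row
    row <- numeric(m)
    row[m] <- 0                              # |s(m, m)| = 1
    row[1] <- log(m - 1) + prev[1]           # |s(m, 1)| = (m-1)!
    if (m > 2L) {
      k <- 2:(m - 1)
      row[k] <- mapply(function(a, b) logsumexp(c(a, b)),
                       prev[k - 1], log(m - 1) + prev[k])
    }
  }
  row
}

#' Ewens distribution of the number of haplotypes
#'
#' P(K = k | theta, n) for k = 1..n: |s(n,k)| theta^k over the rising
#' factorial theta(theta+1)...(theta+n-1).
#'
#' @param n sample size
#' @param theta scaled mutation parameter
#' @return numeric vector of probabilities, k = 1..n
#' @export
ewens_k_distribution <- function(n, theta) {
  if (theta <= 0) return(c(1, rep(0, n - 1L)))
  ls <- log_stirling1_row(n)
  k <- seq_len(n)
  lp <- ls + k * log(theta) - sum(log(theta + 0:(n - 1L)))
  exp(lp)
}

fs_from_k_nh <- function(k_hat, nh, n) {
  pk <- ewens_k_distribution(n, k_hat)
  s_prime <- sum(pk[nh:n])
  list(s_prime = s_prime, fs = log(s_prime) - log1p(-s_prime))
}

#' Fu's Fs test
#'
#' Computes Fs = ln(S'/(1-S')) with S' = Pr(K >= nh_obs | theta-hat, n)
#' under the Ewens sampling distribution, theta-hat being the mean
#' pairwise difference. The p-value is the fraction of neutral
#' constant-size coalescent simulations (infinite sites, theta =
#' theta-hat) whose Fs is less than or equal to the observed value.
#'
#' @param aln a `phd_alignment`
#' @param population population label (NULL = whole alignment)
#' @param n_sim neutral simulations for the p-value (0 skips it)
#' @param seed integer RNG seed
#' @return object of class `phd_fu`: fs, p, s_prime, k_hat, nh_obs, n,
#'   and a `flag` when S' is degenerate (monomorphic sample)
#' @export
fu_fs <- function(aln, population = NULL, n_sim = 5000, seed = 1) {
  if (!is.null(population)) aln <- subset_populations(aln, population)
  n <- n_seq(aln)
  if (n < 4L) stopf("need n >= 4 for Fu's Fs")
  nd <- raw_distance_matrix(aln)
  k_hat <- mean(nd[upper.tri(nd)])
  nh <- collapse_haplotypes(aln)$nh
  flag <- NULL
  if (nh == 1L || k_hat == 0) {
    out <- list(fs = Inf, p = NA_real_, s_prime = 1, k_hat = k_hat,
                nh_obs = nh, n = n,
                flag = "degenerate: S' = 1 (monomorphic or single haplotype)")
    return(structure(out, class = "phd_fu"))
  }
  r <- fs_from_k_nh(k_hat, nh, n)
  if (!is.finite(r$fs))
    flag <- sprintf("S' numerically %s; log-space S' = %.3g",
                    if (r$s_prime >= 1) "1" else "0", r$s_prime)
  p <- NA_real_
  if (n_sim > 0 && is.finite(r$fs)) {
    set.seed(seed)
    sims <- vapply(seq_len(n_sim), function(b) sim_neutral_fs(n, k_hat),
                   numeric(1))
    p <- mean(sims <= r$fs, na.rm = TRUE)
  }
  structure(list(fs = r$fs, p = p, s_prime = r$s_prime, k_hat = k_hat,
                 nh_obs = nh, n = n, n_sim = n_sim, flag = flag),
            class = "phd_fu")
}

## One neutral constant-size coalescent replicate under infinite sites:
## returns the Fs value computed exactly as for data.
sim_neutral_fs <- function(n, theta) {
  gen <- sim_genealogy_sizechange(n)
  nnode <- 2L * n - 1L
  has_par <- which(gen$parent > 0L)
  blen <- gen$time[gen$parent[has_par]] - gen$time[has_par]
  muts <- rpois(length(blen), blen * theta / 2)
  # descendant tip counts per branch (branch below node has_par[j])
  ndesc <- integer(nnode); ndesc[1:n] <- 1L
  for (v in order(gen$time[(n + 1L):nnode]) + n) {
    ch <- which(gen$parent == v)
    ndesc[v] <- sum(ndesc[ch])
  }
  nb <- ndesc[has_par]
  k_sim <- sum(muts * nb * (n - nb)) / (n * (n - 1) / 2)
  # haplotype classes: tips identical iff no mutated branch separates them
  mut_branch <- has_par[muts > 0L]
  sig <- vapply(seq_len(n), function(tip) {
    v <- tip; s <- character(0)
    while (gen$parent[v] > 0L) {
      if (v %in% mut_branch) s <- c(s, as.character(v))
      v <- gen$parent[v]
    }
    paste(s, collapse = ",")
  }, character(1))
  nh_sim <- length(unique(sig))
  if (nh_sim == 1L || k_sim == 0) return(NA_real_)
  fs_from_k_nh(k_sim, nh_sim, n)$fs
}

#' @export
print.phd_fu <- function(x, ...) {
  cat(sprintf("Fu's Fs: %.3f (S' = %.4g, nh = %d, n = %d, theta-hat = %.3f)",
              x$fs, x$s_prime, x$nh_obs, x$n, x$k_hat))
  if (!is.na(x$p)) cat(sprintf(", p = %.4f", x$p))
  if (!is.null(x$flag)) cat(" [", x$flag, "]", sep = "")
  cat("\n")
  invisible(x)
}
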