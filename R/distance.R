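#' Pairwise difference bookkeeping
#'
#' Raw pairwise counts over jointly unambiguous sites (pairwise
#' deletion): differences, transitions split by purine/pyrimidine class,
#' transversions, overlap length and per-pair base frequencies.
#'
#' @param aln a `phd_alignment`
#' @return list of n x n matrices `nd`, `nv`, `p1`, `p2`, `q`, `fA`,
#'   `fC`, `fG`, `fT` with sequence ids as dimnames
#' @keywords internal
pair_counts <- function(aln) {
  out <- .pair_counts_cpp(code_bases(aln$seq))
  out <- lapply(out, function(m) { dimnames(m) <- list(aln$id, aln$id); m })
  out
}

#' Raw pairwise difference matrix
#' @param aln a `phd_alignment`
#' @return symmetric matrix of raw difference counts (pairwise deletion)
#' @export
raw_distance_matrix <- function(aln) pair_counts(aln)$nd

#' Tamura-Nei (1993) distance matrix with optional gamma correction
#'
#' Pairwise TN93 distances, by default with gamma-distributed
#' rate heterogeneity across sites (shape `gamma_alpha`). Base
#' frequencies are estimated per sequence pair (the classic pairwise
#' estimator); `freqs = "alignment"` uses frequencies pooled over the
#' whole alignment instead. Sites with N or gaps are excluded pairwise.
#'
#' @param aln a `phd_alignment` with at least two sequences
#' @param gamma_alpha positive gamma shape, or NULL for no gamma
#'   correction
#' @param freqs "pair" (default) or "alignment"
#' @return object of class `phd_dist`: list with `d` (symmetric distance
#'   matrix, substitutions/site), `labels`, `model`
#' @export
tn93_distance_matrix <- function(aln, gamma_alpha = 0.4,
                                 freqs = c("pair", "alignment")) {
  freqs <- match.arg(freqs)
  if (n_seq(aln) < 2L) stopf("need >= 2 sequences")
  pc <- pair_counts(aln)
  n <- n_seq(aln)
  if (any(pc$nv[upper.tri(pc$nv)] == 0)) {
    ij <- which(upper.tri(pc$nv) & pc$nv == 0, arr.ind = TRUE)[1L, ]
    stopf("overlap error: no jointly unambiguous sites for pair (%s, %s)",
          aln$id[ij[1L]], aln$id[ij[2L]])
  }
  P1 <- pc$p1 / pc$nv; P2 <- pc$p2 / pc$nv; Q <- pc$q / pc$nv
  diag(P1) <- diag(P2) <- diag(Q) <- 0
  if (freqs == "pair") {
    fA <- pc$fA; fC <- pc$fC; fG <- pc$fG; fT <- pc$fT
  } else {
    f <- base_freqs(aln)
    one <- matrix(1, n, n)
    fA <- f["A"] * one; fC <- f["C"] * one; fG <- f["G"] * one; fT <- f["T"] * one
  }
  gR <- fA + fG; gY <- fC + fT
  k1 <- 2 * fA * fG / gR
  k2 <- 2 * fC * fT / gY
  k3 <- 2 * (gR * gY - fA * fG * gY / gR - fC * fT * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  # monomorphic-class guards: k -> 0 with P = 0 contributes 0
  w1[k1 == 0] <- 1; k1[k1 == 0] <- 0
  w2[k2 == 0] <- 1; k2[k2 == 0] <- 0
  diag(w1) <- diag(w2) <- diag(w3) <- 1
  bad <- which((w1 <= 0 | w2 <= 0 | w3 <= 0) & upper.tri(w1), arr.ind = TRUE)
  if (nrow(bad))
    stopf("saturation error: TN93 undefined for pair (%s, %s)",
          aln$id[bad[1L, 1L]], aln$id[bad[1L, 2L]])
  if (is.null(gamma_alpha)) {
    d <- -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
    model <- "TN93"
  } else {
    if (gamma_alpha <= 0) stopf("gamma_alpha must be positive")
    a <- gamma_alpha
    d <- a * (k1 * (w1^(-1 / a) - 1) + k2 * (w2^(-1 / a) - 1) +
                k3 * (w3^(-1 / a) - 1))
    model <- sprintf("TN93_gamma(%g)", gamma_alpha)
  }
  diag(d) <- 0
  d <- (d + t(d)) / 2
  structure(list(d = d, labels = aln$id, model = model,
                 population = aln$population),
            class = "phd_dist")
}

#' @export
print.phd_dist <- function(x, ...) {
  cat(sprintf("phd_dist: %d x %d, model %s, mean off-diagonal %.5f\n",
              nrow(x$d), ncol(x$d), x$model,
              mean(x$d[upper.tri(x$d)])))
  invisible(x)
}

#' Alignment-wide base frequencies
#' @param aln a `phd_alignment`
#' @return named numeric vector over A, C, G, T (ambiguity ignored)
#' @export
base_freqs <- function(aln) {
  tab <- table(factor(aln$seq, levels = c("A", "C", "G", "T")))
  f <- as.numeric(tab) / sum(tab)
  setNames(f, c("A", "C", "G", "T"))
}

#' Write a distance matrix in square PHYLIP format
#' @param dm a `phd_dist` or square matrix
#' @param path output path
#' @return invisibly, the path
#' @export
write_phylip_dist <- function(dm, path) {
  d <- if (inherits(dm, "phd_dist")) dm$d else dm
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i)
               paste0(formatC(rownames(d)[i], width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = " ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Molecular diversity summary for one population
#'
#' Unbiased haplotype diversity h = n/(n-1) (1 - sum p_i^2) with its
#' Nei (1987) standard deviation; mean raw pairwise differences k
#' (pairwise deletion); nucleotide diversity per site pi = k / L with
#' the Nei (1987) total variance; S variable sites.
#'
#' @param aln a `phd_alignment`
#' @param population population label (NULL = whole alignment)
#' @param exact passed to [collapse_haplotypes()]
#' @param model "raw" (default; the convention under which pi times the
#'   compared length equals k exactly) or "tn93" for model-corrected
#'   per-site diversity (gamma shape 0.4)
#' @return object of class `phd_diversity`: list n, nh, h, h_sd, k, pi,
#'   pi_sd, S
#' @export
diversity_summary <- function(aln, population = NULL, exact = FALSE,
                              model = c("raw", "tn93")) {
  model <- match.arg(model)
  if (!is.null(population)) aln <- subset_populations(aln, population)
  n <- n_seq(aln)
  if (n < 2L) stopf("sample-size error: need n >= 2, got %d", n)
  hap <- collapse_haplotypes(aln, exact = exact)
  p <- hap$counts / n
  sum2 <- sum(p^2)
  h <- n / (n - 1) * (1 - sum2)
  # Nei (1987) eq. 8.12
  vh <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - sum2^2) + sum2 - sum2^2)
  pc <- pair_counts(aln)
  ut <- upper.tri(pc$nd)
  k <- mean(pc$nd[ut])
  L <- mean(pc$nv[ut])   # effective compared length under pairwise deletion
  pi <- if (model == "raw") k / L else {
    dtn <- tn93_distance_matrix(aln)$d
    mean(dtn[ut])
  }
  # Nei (1987) eq. 10.7 total variance of pi
  vpi <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  S <- classify_sites(aln)$summary$S
  structure(list(population = population %||% "(all)", n = n, nh = hap$nh,
                 h = h, h_sd = sqrt(max(vh, 0)), k = k, pi = pi,
                 pi_sd = sqrt(max(vpi, 0)), S = S, L = L),
            class = "phd_diversity")
}

#' @export
print.phd_diversity <- function(x, ...) {
  cat(sprintf(paste0("%s: n = %d, nh = %d, h = %.3f (SD %.3f), ",
                     "k = %.3f, pi = %.5f (SD %.5f), S = %d\n"),
              x$population, x$n, x$nh, x$h, x$h_sd, x$k, x$pi, x$pi_sd, x$S))
  invisible(x)
}

#' Per-population diversity table
#'
#' One row per population: the "genetic variability" block of the usual
#' summary table (n, nh, h, SD, pi, SD, k, S).
#'
#' @param aln a `phd_alignment`
#' @param path optional TSV output path
#' @return data.frame
#' @export
diversity_table <- function(aln, path = NULL) {
  pops <- unique(aln$population)
  rows <- lapply(pops, function(p) {
    d <- diversity_summary(aln, p)
    data.frame(population = p, n = d$n, nh = d$nh, h = round(d$h, 3),
               h_sd = round(d$h_sd, 3), pi = signif(d$pi, 3),
               pi_sd = signif(d$pi_sd, 3), k = round(d$k, 3), S = d$S)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
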