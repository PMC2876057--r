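## Analysis of molecular variance on squared molecular distances
## (Excoffier-style sums of squares computed from a distance matrix).

ss_sets <- function(d2, sets) {
  sum(vapply(sets, function(ix) sum(d2[ix, ix, drop = FALSE]) / (2 * length(ix)),
             numeric(1)))
}

amova2_components <- function(d2, lab) {
  N <- length(lab)
  sets <- split(seq_len(N), lab)
  P <- length(sets)
  np <- lengths(sets)
  ss_t <- sum(d2) / (2 * N)
  ss_w <- ss_sets(d2, sets)
  ss_a <- ss_t - ss_w
  s2w <- ss_w / (N - P)
  nc <- (N - sum(np^2) / N) / (P - 1)
  s2a <- (ss_a / (P - 1) - s2w) / nc
  phi <- s2a / (s2a + s2w)
  list(phi_st = phi, s2a = s2a, s2w = s2w,
       ss = c(among = ss_a, within = ss_w, total = ss_t))
}

#' Pairwise Phi_ST with a permutation test
#'
#' Phi_ST between two populations from AMOVA variance components on
#' squared molecular distances. The null distribution permutes
#' individuals between the two populations; the p-value is the
#' +1-corrected proportion of permuted statistics at least as large as
#' the observed one.
#'
#' @param dm a `phd_dist` (carries population labels), or a square
#'   distance matrix plus `populations`
#' @param pair character vector of two population labels
#' @param n_perm number of permutations (the conventional default for
#'   this analysis is 20100; tests use fewer)
#' @param seed integer RNG seed
#' @param populations population label per row of `dm` when `dm` is a
#'   plain matrix
#' @return object of class `phd_phi`: list phi_st, p, n_perm, pair
#' @export
pairwise_phi_st <- function(dm, pair, n_perm = 20100, seed = 1,
                            populations = NULL) {
  if (n_perm < 1) stopf("parameter error: n_perm must be >= 1")
  d <- if (inherits(dm, "phd_dist")) dm$d else dm
  populations <- if (inherits(dm, "phd_dist")) dm$population else populations
  stopifnot(length(pair) == 2L)
  keep <- populations %in% pair
  lab <- populations[keep]
  if (any(table(factor(lab, levels = pair)) < 2L))
    stopf("size error: both populations need >= 2 sequences")
  d2 <- d[keep, keep, drop = FALSE]^2
  obs <- amova2_components(d2, lab)$phi_st
  set.seed(seed)
  N <- length(lab)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    pl <- sample(lab)
    if (amova2_components(d2, pl)$phi_st >= obs - 1e-12) hits <- hits + 1L
  }
  structure(list(phi_st = obs, p = (hits + 1) / (n_perm + 1),
                 n_perm = n_perm, pair = pair),
            class = "phd_phi")
}

#' @export
print.phd_phi <- function(x, ...) {
  cat(sprintf("Phi_ST(%s, %s) = %.4f, p = %.4g (%d permutations)%s\n",
              x$pair[1], x$pair[2], x$phi_st, x$p, x$n_perm,
              sig_stars(x$p)))
  invisible(x)
}

#' All pairwise Phi_ST values
#'
#' @inheritParams pairwise_phi_st
#' @return list with `phi` (symmetric matrix), `p` (matrix), and a long
#'   `table` data.frame with significance stars
#' @export
phi_st_matrix <- function(dm, n_perm = 20100, seed = 1) {
  pops <- unique(dm$population)
  k <- length(pops)
  phi <- p <- matrix(0, k, k, dimnames = list(pops, pops))
  diag(p) <- 1
  rows <- list()
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    r <- pairwise_phi_st(dm, c(pops[i], pops[j]), n_perm,
                         seed + 1000L * i + j)
    phi[i, j] <- phi[j, i] <- r$phi_st
    p[i, j] <- p[j, i] <- r$p
    rows[[length(rows) + 1L]] <-
      data.frame(pop1 = pops[i], pop2 = pops[j],
                 phi_st = round(r$phi_st, 4), p = r$p,
                 stars = sig_stars(r$p), stringsAsFactors = FALSE)
  }
  list(phi = phi, p = p, table = do.call(rbind, rows))
}

#' Hierarchical (three-level) AMOVA
#'
#' Variance decomposition among groups (Phi_CT), among populations
#' within groups (Phi_SC) and within populations, with the classic
#' permutation schemes: whole populations among groups for Phi_CT,
#' individuals among populations within groups for Phi_SC, individuals
#' among all populations for Phi_ST.
#'
#' @param dm a `phd_dist`, or a plain square distance matrix with
#'   `populations` giving the label per row
#' @param groups named character vector: population label -> group label
#' @param n_perm permutations per statistic
#' @param seed integer RNG seed
#' @param populations population label per row when `dm` is a plain
#'   matrix
#' @return object of class `phd_amova`: Phi statistics, variance
#'   components (sigma2), sums of squares and p-values
#' @export
hierarchical_amova <- function(dm, groups, n_perm = 1000, seed = 1,
                               populations = NULL) {
  d2 <- (if (inherits(dm, "phd_dist")) dm$d else dm)^2
  pop <- if (inherits(dm, "phd_dist")) dm$population else populations
  if (!all(pop %in% names(groups)))
    stopf("groups must map every population label")
  grp <- unname(groups[pop])
  if (length(unique(grp)) < 2L)
    stopf("hierarchy error: a single group; use pairwise_phi_st")
  obs <- amova3_components(d2, pop, grp)
  set.seed(seed)
  N <- length(pop)
  hits <- c(ct = 0L, sc = 0L, st = 0L)
  pops_by_grp <- split(unique(pop), groups[unique(pop)])
  for (b in seq_len(n_perm)) {
    # Phi_ST: individuals among all populations
    perm_pop <- sample(pop)
    st <- amova3_components(d2, perm_pop, unname(groups[perm_pop]))$phi_st
    if (st >= obs$phi_st - 1e-12) hits["st"] <- hits["st"] + 1L
    # Phi_SC: individuals among populations within groups
    perm2 <- pop
    for (g in unique(grp)) {
      ix <- which(grp == g)
      perm2[ix] <- sample(pop[ix])
    }
    sc <- amova3_components(d2, perm2, grp)$phi_sc
    if (sc >= obs$phi_sc - 1e-12) hits["sc"] <- hits["sc"] + 1L
    # Phi_CT: whole populations among groups
    upops <- unique(pop)
    gsizes <- lengths(pops_by_grp)
    shuffled <- sample(upops)
    newg <- setNames(rep(names(pops_by_grp), gsizes), shuffled)
    ct <- amova3_components(d2, pop, unname(newg[pop]))$phi_ct
    if (ct >= obs$phi_ct - 1e-12) hits["ct"] <- hits["ct"] + 1L
  }
  p <- (hits + 1) / (n_perm + 1)
  structure(c(obs, list(p_ct = p[["ct"]], p_sc = p[["sc"]], p_st = p[["st"]],
                        n_perm = n_perm)),
            class = "phd_amova")
}

amova3_components <- function(d2, pop, grp) {
  N <- length(pop)
  pops <- split(seq_len(N), pop)
  grps <- split(seq_len(N), grp)
  P <- length(pops); G <- length(grps)
  np <- lengths(pops)
  ss_t <- sum(d2) / (2 * N)
  ss_wp <- ss_sets(d2, pops)
  ss_wg <- ss_sets(d2, grps)
  ss_ag <- ss_t - ss_wg          # among groups
  ss_apwg <- ss_wg - ss_wp       # among populations within groups
  # expected mean-square coefficients
  grp_of_pop <- tapply(grp, pop, function(x) x[1L])
  ng <- tapply(np, grp_of_pop, sum)          # individuals per group
  sum_np2_by_g <- tapply(np^2, grp_of_pop, sum)
  ncoef2 <- (sum(sum_np2_by_g / ng) - sum(np^2) / N) / (G - 1)
  ncoef3 <- (N - sum(ng^2) / N) / (G - 1)
  s2c <- ss_wp / (N - P)
  if (P == G) {
    # one population per group: the middle level is empty
    s2b <- 0
  } else {
    ncoef <- (N - sum(sum_np2_by_g / ng)) / (P - G)
    s2b <- (ss_apwg / (P - G) - s2c) / ncoef
  }
  s2a <- (ss_ag / (G - 1) - s2c - ncoef2 * s2b) / ncoef3
  tot <- s2a + s2b + s2c
  list(phi_ct = s2a / tot,
       phi_sc = s2b / (s2b + s2c),
       phi_st = (s2a + s2b) / tot,
       sigma2 = c(among_groups = s2a, among_pops_within = s2b,
                  within_pops = s2c),
       ss = c(among_groups = ss_ag, among_pops_within = ss_apwg,
              within_pops = ss_wp, total = ss_t))
}

#' @export
print.phd_amova <- function(x, ...) {
  cat(sprintf("AMOVA: Phi_CT = %.4f (p = %.3g), Phi_SC = %.4f (p = %.3g), Phi_ST = %.4f (p = %.3g)\n",
              x$phi_ct, x$p_ct, x$phi_sc, x$p_sc, x$phi_st, x$p_st))
  cat("variance components:",
      paste(sprintf("%s = %.4g", names(x$sigma2), x$sigma2), collapse = ", "),
      "\n")
  invisible(x)
}

#' Pool temporal replicate samples that show no differentiation
#'
#' Replicates of one location collected in different years are compared
#' by pairwise Phi_ST; replicates that differ from none of the others
#' are merged. Each excluded replicate is then re-tested against the
#' pooled remainder; if it still differs it is kept separate and
#' flagged (the "chaotic genetic patchiness" pattern), otherwise it is
#' merged after all.
#'
#' @param dm a `phd_dist`
#' @param replicates character vector of population labels that are
#'   temporal replicates of one location
#' @param alpha significance level for each pairwise test
#' @param n_perm permutations per test
#' @param seed integer RNG seed
#' @return list with `pooled` (labels merged), `separate` (labels kept
#'   apart, flagged), and `tests` (data.frame of all tests run)
#' @export
pool_temporal_samples <- function(dm, replicates, alpha = 0.05,
                                  n_perm = 1000, seed = 1) {
  if (length(replicates) < 2L)
    return(list(pooled = replicates, separate = character(0),
                tests = data.frame()))
  tests <- list()
  k <- length(replicates)
  pmat <- matrix(1, k, k, dimnames = list(replicates, replicates))
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    r <- pairwise_phi_st(dm, replicates[c(i, j)], n_perm,
                         seed + 37L * i + j)
    pmat[i, j] <- pmat[j, i] <- r$p
    tests[[length(tests) + 1L]] <-
      data.frame(pop1 = replicates[i], pop2 = replicates[j],
                 phi_st = r$phi_st, p = r$p, stage = "pairwise")
  }
  keep <- replicates
  excluded <- character(0)
  repeat {
    nsig <- vapply(keep, function(r)
      sum(pmat[r, setdiff(keep, r)] < alpha), numeric(1))
    if (all(nsig == 0) || length(keep) <= 1L) break
    worst <- keep[which.max(nsig)]
    excluded <- c(excluded, worst)
    keep <- setdiff(keep, worst)
  }
  separate <- character(0)
  for (r in excluded) {
    if (length(keep) == 0L) { separate <- c(separate, r); next }
    # re-test against the pooled remainder
    d <- dm$d; pops <- dm$population
    pops[pops %in% keep] <- "__pooled__"
    res <- pairwise_phi_st(d, c(r, "__pooled__"), n_perm,
                           seed + 101L, populations = pops)
    tests[[length(tests) + 1L]] <-
      data.frame(pop1 = r, pop2 = paste(keep, collapse = "+"),
                 phi_st = res$phi_st, p = res$p, stage = "vs_pooled")
    if (res$p < alpha) separate <- c(separate, r) else keep <- c(keep, r)
  }
  list(pooled = keep, separate = separate,
       tests = do.call(rbind, tests))
}

#' Apply a pooling plan to an alignment
#'
#' Relabels the pooled temporal replicates with a single label.
#' @param aln a `phd_alignment`
#' @param pooled character vector of labels to merge
#' @param label new label for the merged sample
#' @return a `phd_alignment`
#' @export
apply_pooling <- function(aln, pooled, label) {
  pop <- aln$population
  pop[pop %in% pooled] <- label
  alignment(aln$seq, aln$id, pop, aln$year)
}

#' Slatkin-linearised distances and UPGMA population tree
#'
#' D = Phi_ST / (1 - Phi_ST) per population pair (proportional to
#' between-population coalescence time under a simple divergence
#' model); negative Phi_ST is clamped to 0 with a warning. UPGMA
#' (average-linkage) agglomeration yields an ultrametric tree.
#'
#' @param phi symmetric matrix of pairwise Phi_ST values with dimnames
#' @return list with `D` (linearised matrix), `tree` (an `ape` phylo),
#'   `newick` (string)
#' @export
slatkin_upgma <- function(phi) {
  if (!isTRUE(all.equal(phi, t(phi)))) stopf("phi matrix must be symmetric")
  if (any(phi[upper.tri(phi)] >= 1)) {
    ij <- which(phi >= 1 & upper.tri(phi), arr.ind = TRUE)[1L, ]
    stopf("infinite distance: Phi_ST = 1 for pair (%s, %s)",
          rownames(phi)[ij[1]], colnames(phi)[ij[2]])
  }
  if (any(phi[upper.tri(phi)] < 0))
    warnf("negative Phi_ST clamped to 0 in Slatkin linearisation")
  ph <- pmax(phi, 0)
  D <- ph / (1 - ph)
  diag(D) <- 0
  hc <- hclust(as.dist(D), method = "average")
  tree <- ape::as.phylo(hc)
  list(D = D, tree = tree, newick = ape::write.tree(tree))
}

#' Mantel test of isolation by distance
#'
#' Converts pairwise Phi_ST to absolute migrant numbers
#' M = (1 - Phi_ST) / (2 Phi_ST) (haploid/maternal scaling), correlates
#' M with geographic distance, and obtains a permutation p-value by
#' jointly permuting rows and columns of the geographic matrix. Pairs
#' with Phi_ST <= 0 carry an undefined migrant number and are flagged
#' and excluded from the correlation.
#'
#' @param phi symmetric pairwise Phi_ST matrix with dimnames
#' @param geo symmetric geographic distance matrix (e.g. nautical
#'   miles), same labels
#' @param n_perm permutations
#' @param seed integer RNG seed
#' @param exclude optional population label dropped before testing
#' @return object of class `phd_ibd`: list r, r2, p, M (matrix),
#'   excluded_pairs, n_pops
#' @export
mantel_ibd <- function(phi, geo, n_perm = 10000, seed = 1, exclude = NULL) {
  if (!is.null(exclude)) {
    keep <- setdiff(rownames(phi), exclude)
    phi <- phi[keep, keep]; geo <- geo[keep, keep]
  }
  geo <- geo[rownames(phi), rownames(phi)]
  k <- nrow(phi)
  if (k < 4L) warnf("fewer than 4 populations: Mantel null is degenerate")
  M <- matrix(NA_real_, k, k, dimnames = dimnames(phi))
  pos <- phi > 0
  M[pos] <- (1 - phi[pos]) / (2 * phi[pos])
  diag(M) <- NA
  ut <- upper.tri(phi)
  flagged <- which(!pos & ut, arr.ind = TRUE)
  if (nrow(flagged))
    warnf("%d pair(s) with Phi_ST <= 0 excluded from IBD correlation",
          nrow(flagged))
  use <- ut & pos
  if (sum(use) < 3L) stopf("not enough defined pairs for a correlation")
  r_obs <- cor(M[use], geo[use])
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    o <- sample(k)
    gp <- geo[o, o]
    if (abs(cor(M[use], gp[use])) >= abs(r_obs) - 1e-12) hits <- hits + 1L
  }
  structure(list(r = r_obs, r2 = r_obs^2, p = (hits + 1) / (n_perm + 1),
                 M = M, n_pops = k,
                 excluded_pairs = if (nrow(flagged))
                   data.frame(pop1 = rownames(phi)[flagged[, 1]],
                              pop2 = colnames(phi)[flagged[, 2]])
                 else NULL),
            class = "phd_ibd")
}

#' @export
print.phd_ibd <- function(x, ...) {
  cat(sprintf("Mantel IBD over %d populations: r2 = %.3f, p = %.3g\n",
              x$n_pops, x$r2, x$p))
  invisible(x)
}

#' Bonferroni multiple-testing calls
#'
#' @param pvals numeric vector of p-values
#' @param alpha family-wise significance level
#' @return list with `threshold` (alpha / number of tests) and
#'   `significant` (logical vector, p < threshold)
#' @export
bonferroni <- function(pvals, alpha = 0.05) {
  if (!length(pvals)) stopf("empty p-value list")
  thr <- alpha / length(pvals)
  list(threshold = thr, significant = pvals < thr, n_tests = length(pvals))
}
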