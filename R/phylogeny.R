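#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via ape). Slightly negative branch lengths
#' can arise on non-additive inputs; they are clamped to zero on output
#' with a message, after transferring the negative length to the
#' adjacent edge (Kuhner-Felsenstein style).
#'
#' @param dm a `phd_dist` or square symmetric matrix with dimnames
#' @param clamp_negative clamp negative branch lengths (default TRUE)
#' @return an `ape` phylo object (unrooted)
#' @export
nj_tree <- function(dm, clamp_negative = TRUE) {
  d <- if (inherits(dm, "phd_dist")) dm$d else dm
  if (nrow(d) < 3L) stopf("size error: NJ needs >= 3 taxa")
  tr <- ape::nj(as.dist(d))
  if (clamp_negative && any(tr$edge.length < 0)) {
    message(sprintf("NJ produced %d negative branch length(s); clamped",
                    sum(tr$edge.length < 0)))
    for (e in which(tr$edge.length < 0)) {
      # move the negative length onto the sibling/adjacent edges
      node <- tr$edge[e, 1L]
      adj <- setdiff(which(tr$edge[, 1L] == node | tr$edge[, 2L] == node), e)
      tr$edge.length[adj] <- tr$edge.length[adj] + tr$edge.length[e] / length(adj)
      tr$edge.length[e] <- 0
    }
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Bootstrap-supported, outgroup-rooted NJ tree
#'
#' Resamples alignment columns with replacement B times, rebuilds the
#' TN93(+gamma) NJ tree for each replicate, and scores every internal
#' bipartition of the original tree by the percentage of replicates
#' containing it. The tree is rooted on the outgroup.
#'
#' @param aln a `phd_alignment`
#' @param B bootstrap replicates
#' @param seed integer RNG seed
#' @param outgroup sequence id (or vector of ids) to root on
#' @param gamma_alpha gamma shape for the TN93 distances
#' @return list with `tree` (rooted phylo; `node.label` carries percent
#'   support) and `support` (numeric vector)
#' @export
bootstrap_support <- function(aln, B = 1000, seed = 1, outgroup = NULL,
                              gamma_alpha = 0.4) {
  if (!is.null(outgroup) && !all(outgroup %in% aln$id))
    stopf("rooting error: outgroup %s not in alignment",
          paste(setdiff(outgroup, aln$id), collapse = ", "))
  ref <- nj_tree(tn93_distance_matrix(aln, gamma_alpha))
  set.seed(seed)
  L <- n_sites(aln)
  btrees <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(L, L, replace = TRUE)
    baln <- alignment(aln$seq[, cols, drop = FALSE], aln$id,
                      aln$population, aln$year)
    btrees[[b]] <- suppressMessages(
      nj_tree(tn93_distance_matrix(baln, gamma_alpha)))
  }
  class(btrees) <- "multiPhylo"
  cl <- ape::prop.clades(ref, btrees, rooted = FALSE)
  cl[is.na(cl)] <- 0
  support <- 100 * cl / B
  ref$node.label <- round(support, 1)
  tree <- if (!is.null(outgroup))
    ape::root(ref, outgroup = outgroup, resolve.root = TRUE,
              edgelabel = TRUE)
  else ref
  list(tree = tree, support = support)
}

#' Linearise a rooted tree under a clock and convert depths to ages
#'
#' Makes the tree ultrametric by averaging root-to-tip path lengths
#' below each node (each node's height is the mean of its
#' tip-to-node path lengths, constrained to be no greater than its
#' parent's), then converts heights to ages with a pairwise divergence
#' rate: age = height / (rate/2), rate in substitutions/site/Myr
#' between lineage pairs, so the per-lineage rate is rate/2.
#'
#' @param tree a rooted `ape` phylo with branch lengths in
#'   substitutions/site
#' @param divergence_rate_per_myr pairwise divergence rate per Myr
#'   (default 0.021, i.e. 2.1% per Myr)
#' @return list with `tree` (ultrametric, branch lengths in Myr),
#'   `ages_myr` (named node ages), `rate_note` (semantics string)
#' @export
linearize_tree <- function(tree, divergence_rate_per_myr = 0.021) {
  if (!ape::is.rooted(tree)) stopf("rooting error: tree must be rooted")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  # mean node-to-descendant-tip path length, bottom-up
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- setNames(tree$edge.length, tree$edge[, 2L])
  h <- numeric(nnode); ntips_below <- integer(nnode)
  ntips_below[seq_len(ntip)] <- 1L
  ord <- rev(ape::postorder(tree))  # edges, parents first
  nodes_post <- unique(tree$edge[ape::postorder(tree), 1L])
  sumpath <- numeric(nnode)
  for (v in nodes_post) {
    ch <- kids[[as.character(v)]]
    ntips_below[v] <- sum(ntips_below[ch])
    sumpath[v] <- sum(sumpath[ch] + elen[as.character(ch)] * ntips_below[ch])
    h[v] <- sumpath[v] / ntips_below[v]
  }
  # enforce monotonicity child height <= parent height
  root <- ntip + 1L
  for (e in rev(ape::postorder(tree))) {
    pa <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    if (ch > ntip && h[ch] > h[pa]) h[ch] <- h[pa]
  }
  ages <- h / (divergence_rate_per_myr / 2)
  out <- tree
  out$edge.length <- ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]]
  list(tree = out,
       ages_myr = setNames(ages[(ntip + 1L):nnode],
                           paste0("node", (ntip + 1L):nnode)),
       rate_note = sprintf(
         "rate %.4g/site/Myr is pairwise divergence; per-lineage rate %.4g",
         divergence_rate_per_myr, divergence_rate_per_myr / 2))
}
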