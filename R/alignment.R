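#' Construct a labelled sequence alignment
#'
#' The central data container: an aligned set of equal-length nucleotide
#' sequences, each carrying a population label and a collection year.
#' Alphabet is restricted to A, C, G, T, N and the gap character `-`;
#' input is uppercased.
#'
#' @param seqs character vector of sequences (one string each) or a
#'   character matrix with one row per sequence and one column per site
#' @param id character vector of unique sequence identifiers
#' @param population character vector of non-empty population labels
#' @param year integer vector of collection years (NA allowed)
#' @return an object of class `phd_alignment` with elements `id`,
#'   `population`, `year` and `seq` (character matrix, rows = sequences)
#' @export
alignment <- function(seqs, id, population, year = NA_integer_) {
  if (is.matrix(seqs)) {
    seq <- toupper(seqs)
  } else {
    if (length(seqs) == 0L) stopf("empty alignment")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stopf("alignment error: ragged sequence lengths (%s)",
            paste(unique(lens), collapse = ", "))
    seq <- matrix(toupper(unlist(strsplit(seqs, "", fixed = TRUE))),
                  nrow = length(seqs), byrow = TRUE)
  }
  n <- nrow(seq)
  if (n == 0L || ncol(seq) == 0L) stopf("empty alignment")
  if (length(id) != n) stopf("labelling error: %d ids for %d sequences",
                             length(id), n)
  if (anyDuplicated(id)) stopf("labelling error: duplicated sequence ids")
  population <- rep_len(as.character(population), n)
  if (any(is.na(population) | !nzchar(population)))
    stopf("labelling error: empty population label")
  year <- rep_len(suppressWarnings(as.integer(year)), n)
  bad <- setdiff(unique(as.vector(seq)), DNA_ALPHABET)
  if (length(bad))
    stopf("alphabet error: unknown symbol(s) %s", paste(bad, collapse = " "))
  rownames(seq) <- id
  structure(list(id = as.character(id), population = population,
                 year = year, seq = seq),
            class = "phd_alignment")
}

#' @export
print.phd_alignment <- function(x, ...) {
  cat(sprintf("phd_alignment: %d sequences x %d sites\n",
              nrow(x$seq), ncol(x$seq)))
  tab <- table(x$population)
  cat("populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Number of sequences / sites in an alignment
#' @param aln a `phd_alignment`
#' @return integer
#' @export
n_seq <- function(aln) nrow(aln$seq)

#' @rdname n_seq
#' @export
n_sites <- function(aln) ncol(aln$seq)

#' Subset an alignment to one or more populations
#' @param aln a `phd_alignment`
#' @param populations character vector of population labels
#' @return a `phd_alignment`
#' @export
subset_populations <- function(aln, populations) {
  keep <- aln$population %in% populations
  if (!any(keep)) stopf("scope error: no sequences in population(s) %s",
                        paste(populations, collapse = ", "))
  alignment(aln$seq[keep, , drop = FALSE], aln$id[keep],
            aln$population[keep], aln$year[keep])
}

#' Read an aligned FASTA plus a sidecar label table
#'
#' Sequence metadata (population, collection year) is carried in a
#' tab-separated sidecar file with header `id<TAB>population<TAB>year`
#' rather than being packed into FASTA headers.
#'
#' @param fasta path to an aligned multi-FASTA file
#' @param labels path to the labels TSV, or a data.frame with columns
#'   `id`, `population`, `year`
#' @return a `phd_alignment`
#' @export
read_alignment <- function(fasta, labels) {
  dna <- ape::read.FASTA(fasta)
  if (length(dna) == 0L) stopf("empty alignment: no FASTA records in %s", fasta)
  chars <- lapply(as.character(dna), function(x) toupper(x))
  lens <- lengths(chars)
  if (length(unique(lens)) != 1L)
    stopf("alignment error: ragged sequence lengths (%s)",
          paste(unique(lens), collapse = ", "))
  seq <- do.call(rbind, chars)
  if (is.character(labels)) labels <- read.delim(labels, stringsAsFactors = FALSE)
  need <- c("id", "population", "year")
  if (!all(need %in% names(labels)))
    stopf("labelling error: labels table must have columns %s",
          paste(need, collapse = ", "))
  ids <- names(dna)
  m <- match(ids, labels$id)
  if (anyNA(m))
    stopf("labelling error: id(s) missing from labels: %s",
          paste(ids[is.na(m)], collapse = ", "))
  alignment(seq, ids, labels$population[m], labels$year[m])
}

#' Write an alignment as FASTA plus labels TSV
#' @param aln a `phd_alignment`
#' @param fasta output FASTA path
#' @param labels output labels TSV path (optional)
#' @return invisibly, the FASTA path
#' @export
write_alignment <- function(aln, fasta, labels = NULL) {
  lines <- character(2L * n_seq(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", aln$id)
  lines[c(FALSE, TRUE)] <- apply(aln$seq, 1L, paste, collapse = "")
  writeLines(lines, fasta)
  if (!is.null(labels)) {
    write.table(data.frame(id = aln$id, population = aln$population,
                           year = aln$year),
                labels, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}

#' Collapse sequences into haplotypes
#'
#' Distinct sequences are grouped into haplotypes. By default `N` acts as
#' a wildcard: sequences are first grouped by exact identity, then groups
#' whose members are compatible site-by-site (differing only where one
#' carries N or a gap) are merged transitively. This avoids inflating the
#' haplotype count through sequencing ambiguity; `exact = TRUE` disables
#' the wildcard merge.
#'
#' @param aln a `phd_alignment`
#' @param populations optional subset of population labels (default: all)
#' @param exact logical; if TRUE, haplotype identity is exact string match
#' @return an object of class `phd_haplotypes`: `counts` (named integer
#'   vector per haplotype), `n`, `nh`, `membership` (list of member ids
#'   per haplotype), `assignment` (haplotype per sequence id)
#' @export
collapse_haplotypes <- function(aln, populations = NULL, exact = FALSE) {
  if (!is.null(populations)) aln <- subset_populations(aln, populations)
  n <- n_seq(aln)
  strs <- apply(aln$seq, 1L, paste, collapse = "")
  grp <- match(strs, unique(strs))
  if (!exact && any(aln$seq %in% c("N", "-"))) {
    reps <- aln$seq[match(seq_along(unique(strs)), grp), , drop = FALSE]
    g <- length(unique(strs))
    parent <- seq_len(g)
    find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
    amb <- reps %in% c("N", "-"); dim(amb) <- dim(reps)
    for (i in seq_len(g - 1L)) for (j in seq.int(i + 1L, g)) {
      ok <- all(reps[i, ] == reps[j, ] | amb[i, ] | amb[j, ])
      if (ok) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <- min(ri, rj) }
    }
    grp <- vapply(grp, find, 1L)
    grp <- match(grp, unique(grp))
  }
  hap_ids <- sprintf("H%03d", seq_along(unique(grp)))
  assignment <- setNames(hap_ids[grp], aln$id)
  membership <- split(aln$id, assignment)[hap_ids]
  counts <- setNames(lengths(membership), hap_ids)
  structure(list(counts = counts, n = n, nh = length(counts),
                 membership = membership, assignment = assignment),
            class = "phd_haplotypes")
}

#' @export
print.phd_haplotypes <- function(x, ...) {
  cat(sprintf("phd_haplotypes: n = %d, nh = %d\n", x$n, x$nh))
  cat("spectrum:", paste(sort(unname(x$counts), decreasing = TRUE),
                         collapse = " "), "\n")
  invisible(x)
}

#' Classify alignment sites
#'
#' Sites are invariant, singleton or parsimony-informative; variable
#' sites additionally carry a substitution type (transition,
#' transversion, or both) derived from the purine/pyrimidine classes of
#' the observed states. Ambiguous bases (N, gaps) are ignored per site.
#'
#' @param aln a `phd_alignment` with at least two sequences
#' @return an object of class `phd_sites`: data.frame `sites` (position,
#'   category, type) and a `summary` list with tallies: `S` variable
#'   sites, `singleton`, `parsimony_informative`, site counts by type,
#'   and `min_changes` (parsimony lower bound, sum of states-1)
#' @export
classify_sites <- function(aln) {
  if (n_seq(aln) < 2L) stopf("need >= 2 sequences to classify sites")
  L <- n_sites(aln)
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  category <- character(L); type <- rep(NA_character_, L)
  minch <- integer(L)
  for (s in seq_len(L)) {
    col <- aln$seq[, s]
    col <- col[col %in% c("A", "C", "G", "T")]
    tab <- table(col)
    if (length(tab) < 2L) { category[s] <- "invariant"; next }
    category[s] <- if (sum(tab >= 2L) >= 2L) "parsimony_informative" else "singleton"
    minch[s] <- length(tab) - 1L
    st <- names(tab)
    pairs <- combn(st, 2L)
    ts <- purine[pairs[1L, ]] == purine[pairs[2L, ]]
    type[s] <- if (all(ts)) "transition" else if (!any(ts)) "transversion" else "both"
  }
  sites <- data.frame(position = seq_len(L), category = category, type = type,
                      stringsAsFactors = FALSE)
  summary <- list(
    S = sum(category != "invariant"),
    singleton = sum(category == "singleton"),
    parsimony_informative = sum(category == "parsimony_informative"),
    transition_sites = sum(type == "transition", na.rm = TRUE),
    transversion_sites = sum(type == "transversion", na.rm = TRUE),
    both_sites = sum(type == "both", na.rm = TRUE),
    min_changes = sum(minch))
  structure(list(sites = sites, summary = summary), class = "phd_sites")
}

#' @export
print.phd_sites <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("phd_sites: %d variable (%d singleton + %d parsimony-",
                     "informative);\n  site types: %d transition, %d ",
                     "transversion, %d mixed; >= %d changes\n"),
              s$S, s$singleton, s$parsimony_informative, s$transition_sites,
              s$transversion_sites, s$both_sites, s$min_changes))
  invisible(x)
}

#' Detect doublet substitutions on adjacent sites
#'
#' Reports adjacent variable-site pairs whose minority states co-occur in
#' exactly the same set of sequences (e.g. an AT->TA change carried
#' jointly by the same haplotypes), the signature of a two-nucleotide
#' mutation event.
#'
#' @param aln a `phd_alignment`
#' @return data.frame with columns `pos1`, `pos2`, `pattern`
#'   (e.g. "AT->TA") and `n_carriers`
#' @export
detect_doublets <- function(aln) {
  L <- n_sites(aln)
  out <- data.frame(pos1 = integer(), pos2 = integer(),
                    pattern = character(), n_carriers = integer(),
                    stringsAsFactors = FALSE)
  carriers <- vector("list", L); major <- minor <- rep(NA_character_, L)
  for (s in seq_len(L)) {
    col <- aln$seq[, s]
    ok <- col %in% c("A", "C", "G", "T")
    tab <- sort(table(col[ok]), decreasing = TRUE)
    if (length(tab) < 2L) next
    major[s] <- names(tab)[1L]
    carriers[[s]] <- which(ok & col != major[s])
    minor[s] <- paste(sort(unique(col[carriers[[s]]])), collapse = "/")
  }
  for (s in seq_len(L - 1L)) {
    c1 <- carriers[[s]]; c2 <- carriers[[s + 1L]]
    if (is.null(c1) || is.null(c2) || !length(c1)) next
    if (identical(c1, c2)) {
      out[nrow(out) + 1L, ] <- list(s, s + 1L,
        sprintf("%s%s->%s%s", major[s], major[s + 1L], minor[s], minor[s + 1L]),
        length(c1))
    }
  }
  out
}
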