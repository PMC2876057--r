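#' @useDynLib phylodem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim pgamma rexp runif rbinom rpois rmultinom sd
#'   cor hclust as.dist setNames dist qgamma quantile rnorm
#' @importFrom utils read.delim write.table combn head tail
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Integer-code a character alignment matrix
#'
#' A, C, G, T map to 0..3; N and gaps map to -1 (treated as missing under
#' pairwise deletion).
#' @param seq character matrix of single upper-case bases
#' @return integer matrix of the same dimension
#' @keywords internal
code_bases <- function(seq) {
  m <- match(seq, c("A", "C", "G", "T")) - 1L
  m[is.na(m)] <- -1L
  dim(m) <- dim(seq)
  dimnames(m) <- dimnames(seq)
  m
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Deterministic fingerprint of a character vector (md5 of its bytes)
#' @keywords internal
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(x), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Significance stars following the usual population-genetics table style
#' (* p < 0.05, ** p < 0.001)
#' @param p numeric vector of p-values
#' @param cuts two cut points for one and two stars
#' @return character vector
#' @export
sig_stars <- function(p, cuts = c(0.05, 0.001)) {
  ifelse(p < cuts[2], "**", ifelse(p < cuts[1], "*", ""))
}
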