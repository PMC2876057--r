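## Small tabular writers and plots for the module outputs.

#' Write a haplotype table
#'
#' One row per haplotype: id, copy count, comma-separated member
#' sequence ids.
#' @param hap a `phd_haplotypes`
#' @param path output TSV path
#' @return invisibly, the path
#' @export
write_haplotype_table <- function(hap, path) {
  df <- data.frame(haplotype_id = names(hap$counts),
                   count = unname(hap$counts),
                   member_ids = vapply(hap$membership, paste, character(1),
                                       collapse = ","))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-site classification report
#' @param sites a `phd_sites`
#' @param path output TSV path
#' @return invisibly, the path
#' @export
write_site_report <- function(sites, path) {
  write.table(sites$sites, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a mismatch histogram (and optionally a fitted curve) as TSV
#' @param hist a `phd_mismatch`
#' @param path output TSV path
#' @param fit optional `phd_demfit`; adds the expected frequencies
#' @return invisibly, the path
#' @export
write_mismatch_table <- function(hist, path, fit = NULL) {
  df <- data.frame(differences = as.integer(names(hist$counts)),
                   pairs = unname(hist$counts),
                   frequency = unname(hist$counts) / hist$n_pairs)
  if (!is.null(fit)) df$expected <- expected_curve_of(fit, df$differences)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

expected_curve_of <- function(fit, classes) {
  if (fit$model == "sudden_expansion")
    mismatch_expected_demographic(classes, fit$tau, fit$theta0, fit$theta1)
  else
    mismatch_expected_spatial(classes, fit$tau, fit$theta, fit$M)
}

#' Plot a mismatch distribution with an optional fitted expectation
#' @param x a `phd_mismatch`
#' @param fit optional `phd_demfit` overlay
#' @param ... passed to [graphics::barplot()]
#' @return invisibly, the bar midpoints
#' @export
plot.phd_mismatch <- function(x, fit = NULL, ...) {
  freq <- unname(x$counts) / x$n_pairs
  mids <- graphics::barplot(freq, names.arg = names(x$counts),
                            xlab = "pairwise differences",
                            ylab = "frequency", border = NA, ...)
  if (!is.null(fit)) {
    cls <- as.integer(names(x$counts))
    graphics::lines(mids, expected_curve_of(fit, cls), lwd = 2)
  }
  invisible(mids)
}

#' Write the marginal posterior grids of an IM run as TSV
#'
#' One file per parameter (theta, M, T): bin midpoint and posterior
#' mass.
#' @param im a `phd_im`
#' @param prefix path prefix; files are `<prefix>_<param>.tsv`
#' @return invisibly, the written paths
#' @export
write_im_posteriors <- function(im, prefix) {
  paths <- character(0)
  for (v in names(im$grids)) {
    g <- im$grids[[v]]
    p <- sprintf("%s_%s.tsv", prefix, v)
    write.table(data.frame(mid = g$mid, posterior = g$density),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Plot the marginal posteriors of an IM run
#' @param x a `phd_im`
#' @param ... passed to [graphics::plot()]
#' @return invisibly, NULL
#' @export
plot.phd_im <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  for (v in names(x$grids)) {
    g <- x$grids[[v]]
    graphics::plot(g$mid, g$density, type = "h", xlab = v,
                   ylab = "posterior mass",
                   main = sprintf("%s (mode %.2f)", v, x$modes[[v]]), ...)
  }
  invisible(NULL)
}
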