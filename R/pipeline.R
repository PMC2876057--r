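#' Build a pipeline run configuration
#'
#' A structured configuration for the full workflow. Accepts a YAML
#' file path or a named list; unspecified fields take the defaults
#' below. Fields:
#' \describe{
#'   \item{fasta, labels}{input alignment and label-table paths}
#'   \item{out_dir}{output directory for the report bundle}
#'   \item{temporal_replicates}{named list: location -> character vector
#'     of replicate population labels to consider for pooling}
#'   \item{groups}{named character vector population -> region group for
#'     the hierarchical AMOVA}
#'   \item{geo}{path to a TSV of pairwise geographic distances (square
#'     matrix with header), or NULL to skip IBD}
#'   \item{ibd_exclude}{population dropped from the Mantel test}
#'   \item{alpha}{significance level}
#'   \item{n_perm, n_boot, fu_sims}{permutation / bootstrap / neutral
#'     simulation counts}
#'   \item{gamma_alpha}{gamma shape for TN93 distances}
#'   \item{rate, L, generation_years}{molecular-clock rate model}
#'   \item{outgroup}{sequence id(s) used to root the haplotype tree
#'     (NULL: unrooted, no linearisation)}
#'   \item{nj_bootstrap}{bootstrap replicates for the haplotype tree}
#'   \item{im_pairs}{list of 2-vectors of population labels for the
#'     isolation-with-migration analysis (NULL: none)}
#'   \item{im}{list passed to [im_config()]}
#'   \item{seed}{master seed; every stage derives its own stream}
#' }
#'
#' @param config path to a YAML file or a named list
#' @return object of class `phd_runconfig`
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(fasta = NULL, labels = NULL, out_dir = "phylodem_out",
                   temporal_replicates = NULL, groups = NULL, geo = NULL,
                   ibd_exclude = NULL, alpha = 0.05, n_perm = 1000,
                   n_boot = 200, fu_sims = 1000, gamma_alpha = 0.4,
                   rate = 3.6e-8, L = 648, generation_years = 2,
                   outgroup = NULL, nj_bootstrap = 100, im_pairs = NULL,
                   im = list(), seed = 1)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stopf("config error: unknown field(s) %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  for (f in c("fasta", "labels", "geo"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stopf("config error: %s file not found: %s", f, cfg[[f]])
  structure(cfg, class = "phd_runconfig")
}

stage_log <- function(con, stage, ...) {
  kv <- c(...)
  line <- sprintf("%s stage=%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage, paste(names(kv), kv, sep = "=", collapse = " "))
  writeLines(line, con)
  flush(con)
}

#' Run the full phylogeography / demography workflow
#'
#' Stages, in order: read input, temporal pooling, per-population
#' diversity, pairwise Phi_ST + Bonferroni, hierarchical AMOVA,
#' Slatkin/UPGMA population tree, Mantel IBD, NJ haplotype tree with
#' bootstrap (and clock linearisation when an outgroup is given),
#' mismatch fits (demographic and spatial) with Fu's Fs per population,
#' and optional isolation-with-migration runs. Each output table
#' carries the configuration hash and seed; a stage failure is recorded
#' and dependent stages are skipped.
#'
#' @param cfg a [run_config()] (or list/path accepted by it)
#' @param aln optionally, a ready-made `phd_alignment` instead of
#'   `cfg$fasta`/`cfg$labels`
#' @return invisibly, a list with the per-stage results and a `status`
#'   data.frame
#' @export
run_pipeline <- function(cfg, aln = NULL) {
  if (!inherits(cfg, "phd_runconfig")) cfg <- run_config(cfg)
  if (is.null(aln) && (is.null(cfg$fasta) || is.null(cfg$labels)))
    stopf("config error: fasta and labels (or an alignment) are required")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(vapply(cfg, function(x)
    paste(deparse(x), collapse = ""), character(1)))
  logcon <- file(file.path(cfg$out_dir, "pipeline.log"), open = "wt")
  on.exit(close(logcon))
  results <- list(config_hash = hash)
  status <- list()
  failed <- character(0)
  stamp <- function(df) { df$config_hash <- hash; df$seed <- cfg$seed; df }
  run_stage <- function(name, deps, expr) {
    if (length(intersect(deps, failed))) {
      failed <<- c(failed, name)   # dependents of a skipped stage skip too
      status[[name]] <<- "skipped"
      stage_log(logcon, name, status = "skipped",
                reason = paste(intersect(deps, failed), collapse = "+"))
      return(invisible(NULL))
    }
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- c(failed, name)
      status[[name]] <<- paste("failed:", conditionMessage(res))
      stage_log(logcon, name, status = "failed",
                error = shQuote(conditionMessage(res)))
      invisible(NULL)
    } else {
      status[[name]] <<- "ok"
      stage_log(logcon, name, status = "ok")
      res
    }
  }
  rm_ <- rate_model(cfg$rate, cfg$L, cfg$generation_years)

  results$aln <- run_stage("input", character(0), {
    aln %||% read_alignment(cfg$fasta, cfg$labels)
  })
  if (is.null(results$aln)) {
    status <- data.frame(stage = names(status), status = unlist(status))
    return(invisible(c(results, list(status = status))))
  }
  a <- results$aln

  results$distances <- run_stage("distances", "input",
    tn93_distance_matrix(a, cfg$gamma_alpha))

  results$pooling <- run_stage("pooling", "distances", {
    if (is.null(cfg$temporal_replicates)) NULL else {
      plans <- list()
      for (loc in names(cfg$temporal_replicates)) {
        reps <- cfg$temporal_replicates[[loc]]
        plan <- pool_temporal_samples(results$distances, reps,
                                      alpha = cfg$alpha,
                                      n_perm = cfg$n_perm, seed = cfg$seed)
        plans[[loc]] <- plan
        if (length(plan$pooled) > 1L)
          a <- apply_pooling(a, plan$pooled, loc)
      }
      plans
    }
  })
  if (!is.null(results$pooling)) {
    results$aln_pooled <- a
    results$distances <- run_stage("distances_pooled", "pooling",
      tn93_distance_matrix(a, cfg$gamma_alpha))
  }

  results$diversity <- run_stage("diversity", "input",
    stamp(diversity_table(a, file.path(cfg$out_dir, "diversity.tsv"))))

  results$phi <- run_stage("phi_st", "distances", {
    r <- phi_st_matrix(results$distances, n_perm = cfg$n_perm,
                       seed = cfg$seed)
    bc <- bonferroni(r$table$p, cfg$alpha)
    r$table$significant_bonferroni <- bc$significant
    r$bonferroni_threshold <- bc$threshold
    write.table(stamp(r$table), file.path(cfg$out_dir, "phi_st.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    r
  })

  results$amova <- run_stage("amova", "distances", {
    if (is.null(cfg$groups)) NULL else {
      groups <- unlist(cfg$groups)
      am <- hierarchical_amova(results$distances, groups,
                               n_perm = cfg$n_perm, seed = cfg$seed)
      df <- data.frame(statistic = c("phi_ct", "phi_sc", "phi_st"),
                       value = c(am$phi_ct, am$phi_sc, am$phi_st),
                       p = c(am$p_ct, am$p_sc, am$p_st))
      write.table(stamp(df), file.path(cfg$out_dir, "amova.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      am
    }
  })

  results$upgma <- run_stage("upgma", "phi_st", {
    u <- slatkin_upgma(results$phi$phi)
    writeLines(u$newick, file.path(cfg$out_dir, "upgma_populations.nwk"))
    u
  })

  results$ibd <- run_stage("ibd", "phi_st", {
    if (is.null(cfg$geo)) NULL else {
      geo <- as.matrix(read.delim(cfg$geo, row.names = 1L,
                                  check.names = FALSE))
      mantel_ibd(results$phi$phi, geo, n_perm = cfg$n_perm,
                 seed = cfg$seed, exclude = cfg$ibd_exclude)
    }
  })

  results$tree <- run_stage("nj_tree", "input", {
    hap <- collapse_haplotypes(a)
    reps <- vapply(hap$membership, `[`, character(1), 1L)
    haln <- alignment(a$seq[reps, , drop = FALSE], names(hap$membership),
                      a$population[match(reps, a$id)],
                      a$year[match(reps, a$id)])
    if (!is.null(cfg$outgroup)) {
      og_hap <- unique(hap$assignment[cfg$outgroup])
      bt <- bootstrap_support(haln, B = cfg$nj_bootstrap, seed = cfg$seed,
                              outgroup = og_hap,
                              gamma_alpha = cfg$gamma_alpha)
      lin <- linearize_tree(bt$tree)
      ape::write.tree(lin$tree, file.path(cfg$out_dir,
                                          "nj_haplotypes_linearized.nwk"))
      bt$linearized <- lin
    } else {
      bt <- bootstrap_support(haln, B = cfg$nj_bootstrap, seed = cfg$seed,
                              gamma_alpha = cfg$gamma_alpha)
    }
    ape::write.tree(bt$tree, file.path(cfg$out_dir, "nj_haplotypes.nwk"))
    bt
  })

  results$demography <- run_stage("demography", "input", {
    rows <- list(); fits <- list()
    for (p in unique(a$population)) {
      h <- mismatch_histogram(a, p)
      dem <- fit_demographic_expansion(h, n_boot = cfg$n_boot,
                                       seed = cfg$seed,
                                       rm = rm_)
      spa <- fit_spatial_expansion(h, n_boot = cfg$n_boot,
                                   seed = cfg$seed,
                                   rm = rm_)
      fu <- fu_fs(a, p, n_sim = cfg$fu_sims, seed = cfg$seed)
      fits[[p]] <- list(mismatch = h, demographic = dem, spatial = spa,
                        fu = fu)
      rows[[p]] <- data.frame(
        population = p,
        dem_tau = dem$tau, dem_T_ky = dem$time$ky,
        dem_theta0 = dem$theta0, dem_theta1 = dem$theta1,
        dem_N0 = dem$N0, dem_N1 = dem$N1,
        dem_ssd = dem$ssd, dem_p_ssd = dem$p_ssd %||% NA_real_,
        spa_tau = spa$tau, spa_T_ky = spa$time$ky, spa_theta = spa$theta,
        spa_M = spa$M, spa_m = spa$m, spa_ssd = spa$ssd,
        spa_p_ssd = spa$p_ssd %||% NA_real_,
        fu_fs = fu$fs, fu_p = fu$p)
    }
    tab <- do.call(rbind, rows)
    write.table(stamp(tab), file.path(cfg$out_dir, "demography.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(table = tab, fits = fits)
  })

  results$im <- run_stage("im", "input", {
    if (is.null(cfg$im_pairs)) NULL else {
      ims <- lapply(cfg$im_pairs, function(pr) {
        args <- utils::modifyList(list(seed = cfg$seed), cfg$im)
        run_im_mcmc(a, pr, do.call(im_config, args), rm = rm_)
      })
      tab <- im_summary_table(ims, rm_,
                              path = file.path(cfg$out_dir, "im_summary.tsv"))
      list(runs = ims, table = tab)
    }
  })

  status <- data.frame(stage = names(status), status = unlist(status),
                       row.names = NULL)
  write.table(status, file.path(cfg$out_dir, "status.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(results, list(status = status)))
}
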