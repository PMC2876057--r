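#' Define a coalescent simulation scenario
#'
#' Scenarios mirror the demographic histories the analysis modules are
#' designed to detect: constant size, sudden demographic expansion
#' (theta0 -> theta1 at mutational time tau), an approximate spatial
#' (range) expansion implemented as a finite-island structured
#' coalescent whose demes merge at tau, and a two-deme
#' isolation-with-migration history (split T coalescent units ago,
#' symmetric scaled migration M = 2Nm).
#'
#' Mutational parameters follow the mtDNA control-region setting:
#' finite-sites TN93 (or HKY when `kappa2` equals `kappa1`) with
#' gamma-distributed site rates (shape 0.4) and optional adjacent-site
#' "doublet" hotspots that substitute two neighbouring positions in one
#' event.
#'
#' @param kind one of "constant", "sudden_expansion",
#'   "spatial_expansion_approx", "isolation_with_migration"
#' @param theta scaled population-mutation parameter 2Nu per sequence
#'   (current size for constant/spatial; per deme for IM)
#' @param theta0,theta1,tau sudden-expansion parameters (theta before /
#'   after the expansion, mutational time of the expansion)
#' @param M scaled migration 2Nm (spatial and IM scenarios)
#' @param T_split divergence time in coalescent units of N generations
#'   (IM scenario)
#' @param n samples per deme (length 1 or 2)
#' @param L sequence length in sites
#' @param gamma_alpha gamma shape for site-rate heterogeneity
#' @param kappa1,kappa2 TN93 transition/transversion rate multipliers
#'   (A<->G and C<->T); equal values give HKY
#' @param freqs stationary base frequencies (A, C, G, T); default is an
#'   AT-rich control-region-like composition
#' @param n_demes island count for the spatial approximation
#' @param doublet_hotspots integer vector of left positions of
#'   adjacent-site hotspot pairs, or NULL
#' @param doublet_rate expected doublet events per unit branch length
#'   (substitutions/site) per hotspot pair
#' @param pop_names population label(s) for the emitted samples
#' @return a `phd_scenario` list
#' @export
scenario <- function(kind = c("constant", "sudden_expansion",
                              "spatial_expansion_approx",
                              "isolation_with_migration"),
                     theta = 5, theta0 = NULL, theta1 = NULL, tau = NULL,
                     M = NULL, T_split = NULL, n = 20, L = 648,
                     gamma_alpha = 0.4, kappa1 = 16, kappa2 = 12,
                     freqs = c(A = 0.32, C = 0.21, G = 0.14, T = 0.33),
                     n_demes = 100, doublet_hotspots = NULL,
                     doublet_rate = 0, pop_names = NULL) {
  kind <- match.arg(kind)
  chk <- function(x, nm) if (is.null(x) || any(x < 0))
    stopf("scenario error: %s must be supplied and non-negative for %s", nm, kind)
  if (kind == "sudden_expansion") {
    chk(theta0, "theta0"); chk(theta1, "theta1"); chk(tau, "tau")
    if (theta1 <= 0) stopf("scenario error: theta1 must be positive")
  }
  if (kind == "spatial_expansion_approx") {
    chk(theta, "theta"); chk(M, "M"); chk(tau, "tau")
  }
  if (kind == "isolation_with_migration") {
    chk(theta, "theta"); chk(M, "M"); chk(T_split, "T_split")
    if (length(n) == 1L) n <- c(n, n)
  }
  if (kind %in% c("constant", "spatial_expansion_approx") && theta <= 0)
    stopf("scenario error: theta must be positive")
  freqs <- freqs / sum(freqs)
  if (is.null(pop_names))
    pop_names <- if (kind == "isolation_with_migration") c("deme1", "deme2")
                 else "pop1"
  structure(list(kind = kind, theta = theta, theta0 = theta0,
                 theta1 = theta1, tau = tau, M = M, T_split = T_split,
                 n = n, L = L, gamma_alpha = gamma_alpha, kappa1 = kappa1,
                 kappa2 = kappa2, freqs = freqs, n_demes = n_demes,
                 doublet_hotspots = doublet_hotspots,
                 doublet_rate = doublet_rate, pop_names = pop_names),
            class = "phd_scenario")
}

## ---- genealogy simulation ------------------------------------------------

## Kingman coalescent with piecewise-constant relative size:
## size(t) = 1 for t < t_change, = rel_size after. Times in units of N
## (current) generations. rel_size = 0 collapses all remaining lineages
## at t_change (a star burst), the theta0 = 0 degenerate expansion.
sim_genealogy_sizechange <- function(n, t_change = Inf, rel_size = 1) {
  sim_genealogy_sizechange_rate(n, t_change, 1,
                                if (rel_size == 0) Inf else 1 / rel_size)
}

## per-pair coalescence rates rate1 (t < t_change) and rate2 (after);
## rate2 = Inf collapses all remaining lineages at t_change
sim_genealogy_sizechange_rate <- function(n, t_change = Inf, rate1 = 1,
                                          rate2 = 1) {
  nnode <- 2L * n - 1L
  parent <- integer(nnode); time <- numeric(nnode)
  active <- seq_len(n); nxt <- n + 1L; t <- 0
  while (length(active) > 1L) {
    k <- length(active)
    rate <- if (t < t_change) rate1 else rate2
    w <- if (is.infinite(rate)) 0 else rexp(1L, rate = k * (k - 1) / 2 * rate)
    if (t < t_change && t + w > t_change) { t <- t_change; next }
    t <- t + w
    pick <- sample(k, 2L)
    pair <- active[pick]
    parent[pair] <- nxt; time[nxt] <- t
    active <- c(active[-pick], nxt); nxt <- nxt + 1L
  }
  list(parent = parent, time = time, tmrca = t)
}

## Structured coalescent over `nd` demes of equal size (1 in N-units),
## per-lineage migration rate M/2, demes collapsing into a single
## ancestral deme of size `anc_size` at time t_merge. `deme0` gives the
## starting deme of each sample. Above `strong_mig` the event-by-event
## simulation is replaced by the strong-migration limit (lineages well
## mixed across demes; effective pairwise coalescence rate 1/nd), which
## is both accurate and the only tractable regime at very large M.
sim_genealogy_structured <- function(deme0, M, t_merge, nd, anc_size = 1,
                                     strong_mig = 200) {
  n <- length(deme0)
  if (M >= strong_mig) {
    gen <- sim_genealogy_sizechange_rate(n, t_change = t_merge,
                                         rate1 = 1 / nd,
                                         rate2 = 1 / anc_size)
    gen$n_migrations <- NA_integer_
    return(gen)
  }
  nnode <- 2L * n - 1L
  parent <- integer(nnode); time <- numeric(nnode)
  active <- seq_len(n); deme <- deme0; nxt <- n + 1L; t <- 0
  merged <- FALSE
  n_mig <- 0L
  while (length(active) > 1L) {
    k <- length(active)
    if (!merged) {
      kd <- tabulate(deme, nbins = nd)
      r_coal <- sum(kd * (kd - 1) / 2)
      r_mig <- k * M / 2
      tot <- r_coal + r_mig
      if (tot == 0) { t <- t_merge; merged <- TRUE; next }
      w <- rexp(1L, tot)
      if (t + w > t_merge) { t <- t_merge; merged <- TRUE; next }
      t <- t + w
      if (runif(1L) < r_coal / tot) {
        dsel <- sample.int(nd, 1L, prob = kd * (kd - 1) / 2)
        pick <- sample(which(deme == dsel), 2L)
        pair <- active[pick]
        parent[pair] <- nxt; time[nxt] <- t
        active <- c(active[-pick], nxt)
        deme <- c(deme[-pick], dsel)
        nxt <- nxt + 1L
      } else {
        i <- sample.int(k, 1L)
        newd <- if (nd == 2L) 3L - deme[i] else
          sample(setdiff(seq_len(nd), deme[i]), 1L)
        deme[i] <- newd
        n_mig <- n_mig + 1L
      }
    } else {
      w <- rexp(1L, k * (k - 1) / 2 / anc_size)
      t <- t + w
      pick <- sample(k, 2L)
      pair <- active[pick]
      parent[pair] <- nxt; time[nxt] <- t
      active <- c(active[-pick], nxt); deme <- deme[-pick]
      nxt <- nxt + 1L
    }
  }
  list(parent = parent, time = time, tmrca = t, n_migrations = n_mig)
}

## Pairwise-difference histogram implied by a genealogy under the
## infinite-sites approximation: Poisson(branch length * theta/2)
## mutations per branch, each separating the branch's descendant tips
## from the rest. Used by the parametric bootstrap of the mismatch
## fitters, where only the histogram is needed.
sim_mismatch_hist_gen <- function(gen, theta) {
  nnode <- length(gen$parent)
  ntip <- (nnode + 1L) / 2L
  has_par <- which(gen$parent > 0L)
  blen <- gen$time[gen$parent[has_par]] - gen$time[has_par]
  muts <- rpois(length(blen), blen * theta / 2)
  diffs <- matrix(0L, ntip, ntip)
  desc <- vector("list", nnode)
  for (v in seq_len(ntip)) desc[[v]] <- v
  for (v in order(gen$time[(ntip + 1L):nnode]) + ntip)
    desc[[v]] <- unlist(desc[which(gen$parent == v)], use.names = FALSE)
  for (j in which(muts > 0L)) {
    ix <- desc[[has_par[j]]]
    diffs[ix, -ix] <- diffs[ix, -ix] + muts[j]
  }
  d <- diffs[upper.tri(diffs)] + t(diffs)[upper.tri(diffs)]
  mx <- max(d)
  structure(list(counts = setNames(tabulate(d + 1L, nbins = mx + 1L), 0:mx),
                 n_pairs = length(d), n = ntip),
            class = "phd_mismatch")
}

genealogy_tree_length <- function(gen) {
  nn <- length(gen$parent)
  has_par <- gen$parent > 0L
  sum(gen$time[gen$parent[has_par]] - gen$time[which(has_par)])
}

## ---- finite-sites mutation -----------------------------------------------

#' Discrete-gamma site-rate categories (median method, mean-normalised)
#' @keywords internal
gamma_rates <- function(alpha, k = 8L) {
  r <- qgamma((2 * seq_len(k) - 1) / (2 * k), shape = alpha, rate = alpha)
  r / mean(r)
}

#' TN93 transition-probability matrix (R interface to the C++ kernel)
#' @param t branch length in expected substitutions per site
#' @param freqs base frequencies (A, C, G, T)
#' @param kappa1,kappa2 transition rate multipliers
#' @return 4 x 4 matrix, rows = from-state in A, C, G, T order
#' @export
tn93_pmatrix <- function(t, freqs, kappa1, kappa2 = kappa1) {
  .tn93_pmat_cpp(t, freqs / sum(freqs), kappa1, kappa2)
}

## Evolve integer-coded sequences (1..4 = A,C,G,T) down a genealogy.
## brlen_scale converts N-unit times to substitutions/site.
mutate_down_tree <- function(gen, sc, brlen_scale, root_seq = NULL) {
  nnode <- length(gen$parent)
  ntip <- (nnode + 1L) / 2L
  rates <- gamma_rates(sc$gamma_alpha)
  ncat <- length(rates)
  sitecat <- sample.int(ncat, sc$L, replace = TRUE)
  seqs <- matrix(0L, nnode, sc$L)
  root <- which(gen$parent == 0L)
  seqs[root, ] <- root_seq %||%
    sample.int(4L, sc$L, replace = TRUE, prob = sc$freqs)
  # preorder: parents before children; nodes are created in time order so
  # descending node index visits parents first among internals
  # parents first; ties in time (simultaneous coalescence bursts) are
  # broken by node index, parents having been created later
  ord <- order(gen$time[(ntip + 1L):nnode], (ntip + 1L):nnode,
               decreasing = TRUE) + ntip
  for (v in c(ord, seq_len(ntip))) {
    if (v == root) next
    pa <- gen$parent[v]
    bl <- (gen$time[pa] - gen$time[v]) * brlen_scale
    s <- seqs[pa, ]
    if (bl > 0) {
      for (cc in seq_len(ncat)) {
        ix <- which(sitecat == cc)
        if (!length(ix)) next
        P <- tn93_pmatrix(bl * rates[cc], sc$freqs, sc$kappa1, sc$kappa2)
        for (b in 1:4) {
          jx <- ix[s[ix] == b]
          if (length(jx))
            s[jx] <- sample.int(4L, length(jx), replace = TRUE, prob = P[b, ])
        }
      }
      if (length(sc$doublet_hotspots) && sc$doublet_rate > 0) {
        for (hp in sc$doublet_hotspots) {
          nev <- rpois(1L, sc$doublet_rate * bl)
          if (nev %% 2L == 1L) {   # net effect of an odd number of swaps
            a <- s[hp]; b2 <- s[hp + 1L]
            if (a != b2) { s[hp] <- b2; s[hp + 1L] <- a }
            else { nb <- sample(setdiff(1:4, a), 1L); s[hp] <- s[hp + 1L] <- nb }
          }
        }
      }
    }
    seqs[v, ] <- s
  }
  seqs[seq_len(ntip), , drop = FALSE]
}

#' Simulate one sample under a scenario
#'
#' Draws a coalescent genealogy under the scenario, places mutations as
#' a finite-sites TN93/HKY process with gamma site rates, and returns a
#' labelled alignment plus a truth record (generating parameters and
#' realised genealogy summaries).
#'
#' @param sc a `phd_scenario`
#' @param seed integer RNG seed (NULL = use current RNG state)
#' @param id_prefix prefix for sequence ids
#' @param year collection year to record
#' @return list with `alignment` (a `phd_alignment`) and `truth` (list)
#' @export
simulate_sample <- function(sc, seed = NULL, id_prefix = "s", year = 2000L) {
  if (!is.null(seed)) set.seed(seed)
  if (sc$kind == "constant") {
    gen <- sim_genealogy_sizechange(sc$n[1L])
    scale <- sc$theta / (2 * sc$L)
    deme_lab <- rep(sc$pop_names[1L], sc$n[1L])
  } else if (sc$kind == "sudden_expansion") {
    gen <- sim_genealogy_sizechange(sc$n[1L],
                                    t_change = sc$tau / sc$theta1,
                                    rel_size = sc$theta0 / sc$theta1)
    scale <- sc$theta1 / (2 * sc$L)
    deme_lab <- rep(sc$pop_names[1L], sc$n[1L])
  } else if (sc$kind == "spatial_expansion_approx") {
    gen <- sim_genealogy_structured(rep(1L, sc$n[1L]), sc$M,
                                    t_merge = sc$tau / sc$theta,
                                    nd = sc$n_demes)
    scale <- sc$theta / (2 * sc$L)
    deme_lab <- rep(sc$pop_names[1L], sc$n[1L])
  } else {
    gen <- sim_genealogy_structured(rep(c(1L, 2L), sc$n[1:2]), sc$M,
                                    t_merge = sc$T_split, nd = 2L)
    scale <- sc$theta / (2 * sc$L)
    deme_lab <- rep(sc$pop_names[1:2], sc$n[1:2])
  }
  ntip <- length(deme_lab)
  seqs <- mutate_down_tree(gen, sc, scale)
  chars <- matrix(c("A", "C", "G", "T")[seqs], nrow = ntip)
  ids <- sprintf("%s%03d", id_prefix, seq_len(ntip))
  aln <- alignment(chars, ids, deme_lab, year)
  truth <- list(scenario = sc[setdiff(names(sc), "freqs")],
                tmrca = gen$tmrca,
                tree_length = genealogy_tree_length(gen),
                n_migrations = gen$n_migrations %||% 0L)
  list(alignment = aln, truth = truth)
}

#' Generate a study-like multi-population data set
#'
#' Emits temporal-replicate samples from five locations along a coast
#' (SIN 2003/2004/2008, MICH 2002, OAX 2003/2005, CH 2003/2004,
#' PE 2005). All regular samples are drawn from one shared
#' sudden-expansion genealogy, so between-location divergence matches
#' within-location diversity (h near 1, pi about 0.02), the
#' near-panmictic picture typical of a pelagic-fish control region.
#' The SIN 2004 replicate is the designed "odd" sample: its 26
#' sequences descend, through a shallow low-diversity coalescent, from
#' a single founder sequence taken from the same shared genealogy --
#' emulating chaotic genetic patchiness from sweepstakes recruitment.
#' It should be flagged by temporal pooling rather than merged.
#'
#' @param seed integer RNG seed
#' @return list with `alignment` (replicate-labelled), `locations`
#'   (replicate label -> location), `truth` (generating parameters and
#'   genealogy summaries)
#' @export
make_study_like_dataset <- function(seed = 1) {
  set.seed(seed)
  base <- list(tau = 12, theta0 = 2, theta1 = 300)
  odd <- list(tau = 5, theta0 = 0, theta1 = 60)
  reps <- c(SIN03 = 23L, SIN08 = 20L, MICH02 = 31L, OX03 = 25L,
            OX05 = 25L, CH03 = 21L, CH04 = 26L, PE05 = 49L)
  years <- c(2003L, 2008L, 2002L, 2003L, 2005L, 2003L, 2004L, 2005L)
  locs <- c(SIN03 = "SIN", SIN08 = "SIN", MICH02 = "MICH", OX03 = "OAX",
            OX05 = "OAX", CH03 = "CH", CH04 = "CH", PE05 = "PE",
            SIN04 = "SIN04")
  n_main <- sum(reps)
  # one extra tip serves as the founder of the odd SIN04 cohort
  sc_main <- scenario("sudden_expansion", theta0 = base$theta0,
                      theta1 = base$theta1, tau = base$tau,
                      n = n_main + 1L)
  gen <- sim_genealogy_sizechange(n_main + 1L,
                                  t_change = base$tau / base$theta1,
                                  rel_size = base$theta0 / base$theta1)
  seqs <- mutate_down_tree(gen, sc_main, base$theta1 / (2 * sc_main$L))
  founder <- seqs[n_main + 1L, ]
  # SIN04: shallow expansion from a reduced founder pool
  sc_odd <- scenario("sudden_expansion", theta0 = odd$theta0,
                     theta1 = odd$theta1, tau = odd$tau, n = 26L)
  gen_odd <- sim_genealogy_sizechange(26L,
                                      t_change = odd$tau / odd$theta1,
                                      rel_size = odd$theta0 / odd$theta1)
  seqs_odd <- mutate_down_tree(gen_odd, sc_odd,
                               odd$theta1 / (2 * sc_odd$L),
                               root_seq = founder)
  bases <- c("A", "C", "G", "T")
  chars <- rbind(matrix(bases[seqs[seq_len(n_main), ]], nrow = n_main),
                 matrix(bases[seqs_odd], nrow = 26L))
  rep_lab <- c(rep(names(reps), reps), rep("SIN04", 26L))
  yr <- c(rep(years, reps), rep(2004L, 26L))
  ids <- sprintf("%s%03d", tolower(rep_lab),
                 unlist(lapply(c(reps, SIN04 = 26L), seq_len),
                        use.names = FALSE))
  aln <- alignment(chars, ids, rep_lab, yr)
  truth <- list(main = c(base, tmrca = gen$tmrca),
                SIN04 = c(odd, tmrca = gen_odd$tmrca, founder_from = "main"))
  list(alignment = aln, locations = locs, truth = truth)
}
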