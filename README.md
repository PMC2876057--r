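# phylodem

Phylogeography and historical demography from mtDNA control-region
alignments.

Marine fishes with large, mobile populations often look genetically
homogeneous, yet spawning-site fidelity, oceanographic barriers and
Pleistocene climate cycles leave subtle footprints in the hypervariable
mitochondrial control region. phylodem packages the analysis chain
population geneticists apply to such data — from a labelled alignment
to diversity tables, Φ-statistics, expansion dating and coalescent
divergence inference — together with a self-contained coalescent
simulator, so every stage is testable against data with known truth.
It is aimed at researchers analysing intraspecific, maternally
inherited sequence data (and at anyone who wants the component
statistics with explicit, tested conventions).

## What it computes

* **Sequence handling** — aligned FASTA + sidecar label TSV; haplotype
  collapsing (N as wildcard, exact mode available), variable-site
  classification (singleton / parsimony-informative, transitions vs
  transversions), detection of adjacent-site "doublet" substitutions.
* **Diversity** — unbiased haplotype diversity
  h = n/(n−1)(1 − Σpᵢ²), nucleotide diversity π (raw differences,
  pairwise deletion), mean pairwise differences k, with Nei (1987)
  standard deviations; Tamura–Nei (1993) distances with gamma rate
  heterogeneity (default shape 0.4).
* **Structure** — pairwise Φ_ST and three-level AMOVA (Φ_CT, Φ_SC,
  Φ_ST) from squared molecular distances with permutation nulls;
  temporal-replicate pooling with outlier flagging; Slatkin-linearised
  F_ST/(1−F_ST) with UPGMA population trees; Mantel isolation-by-
  distance on migrant numbers M = (1−Φ_ST)/(2Φ_ST); Bonferroni
  control.
* **Demography** — mismatch distributions; least-squares fits of the
  sudden demographic expansion (τ, θ₀, θ₁) and the infinite-island
  spatial expansion (τ, θ, M = 2Nm), with parametric-bootstrap SSD
  tests and τ confidence intervals; Fu's Fs via the exact Ewens
  distribution (log-space Stirling numbers) with coalescent p-values;
  molecular-clock conversions τ = 2uT and θ = 2Nu.
* **Trees** — neighbour-joining with column-bootstrap support,
  outgroup rooting, and clock linearisation at a user-set pairwise
  divergence rate (default 2.1%/Myr).
* **Isolation with migration** — a two-population coalescent MCMC
  (genealogies with explicit migration events; HKY finite-sites
  pruning likelihood in C++) returning marginal posterior grids and
  modes for θ = 2N_ef·u, M = 2N_ef·m and T = t/N_ef, plus a TMRCA
  summary per population pair.
* **Simulation** — constant-size, sudden-expansion, spatial-expansion
  and isolation-with-migration coalescent scenarios with finite-sites
  TN93/HKY mutation, gamma site rates and optional doublet hotspots;
  `make_study_like_dataset()` builds a full multi-population demo data
  set including a planted low-diversity "sweepstakes" replicate.
* **Pipeline** — `run_pipeline()` chains the stages from one
  configuration (YAML or list), stamps every output table with the
  config hash and seed, and isolates stage failures. A thin CLI lives
  at `inst/cli/phylodem.R`.

## Worked example

```r
library(phylodem)

sc  <- scenario("sudden_expansion", tau = 10, theta0 = 1, theta1 = 500, n = 40)
sim <- simulate_sample(sc, seed = 7)

diversity_summary(sim$alignment)
#> (all): n = 40, nh = 39, h = 0.999 (SD 0.006), k = 8.917,
#>        pi = 0.01376 (SD 0.00719), S = 124

h   <- mismatch_histogram(sim$alignment)
fit <- fit_demographic_expansion(h, n_boot = 200, seed = 1, rm = rate_model())
fit
#> sudden_expansion fit: tau = 8.19, theta0 = 0.92, theta1 = 570.3, SSD = 0.00072
#>   bootstrap: p(SSD) = 0.755, tau 95% CI [6.09, 10.57] (200 reps)
#>   expansion time: 175.6 ky (CI 130.6-226.5)

fu_fs(sim$alignment, n_sim = 1000, seed = 1)
#> Fu's Fs: -37.924 (S' = 3.386e-17, nh = 39, n = 40, theta-hat = 8.917), p = 0.0000
```

The sample was generated under a strong expansion (τ = 10) and the
pipeline reads it back as one: near-maximal haplotype diversity with
moderate π, a unimodal mismatch distribution whose fitted crest (τ̂ =
8.2, 95% CI covering the truth) dates the expansion — 176 ky under the
default clock (3.6%/Myr·site, 648 bp, 2-year generations) — a
non-significant SSD lack-of-fit, and a strongly negative Fu's Fs.

The clock conversions themselves are one-liners:

```r
round(tau_to_time(13.4, rate_model())$ky, 1)   #> 287.2
signif(theta_to_N(255.3, rate_model()), 2)     #> 2.7e+06
```

For the full workflow on a study-like data set (temporal pooling →
diversity → Φ_ST/AMOVA → UPGMA → NJ → mismatch/Fs → IM):

```r
ds  <- make_study_like_dataset(seed = 5)
res <- run_pipeline(run_config(list(
  out_dir = "demo_out",
  temporal_replicates = list(SIN = c("SIN03", "SIN04", "SIN08"),
                             OAX = c("OX03", "OX05"), CH = c("CH03", "CH04")),
  groups = list(SIN = "north", SIN04 = "north", MICH02 = "north",
                OAX = "central", CH = "central", PE05 = "south"),
  n_perm = 199, n_boot = 50, fu_sims = 200, nj_bootstrap = 30,
  seed = 11)), aln = ds$alignment)
res$pooling$SIN$separate
#> [1] "SIN04"     # the planted sweepstakes cohort is flagged, not pooled
```

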