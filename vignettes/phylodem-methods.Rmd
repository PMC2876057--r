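---
title: "Models and methods in phylodem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phylodem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phylodem implements the analysis chain routinely applied to
intraspecific mtDNA control-region alignments of marine fishes:
molecular diversity, Φ-statistic population structure, historical
demography from mismatch distributions and Fu's Fs, distance-based
trees, and a two-population isolation-with-migration sampler. This
vignette records the models, the parameter conventions, the numerical
choices, and the places where a design decision was genuinely open.

## Data model and conventions

An alignment is a set of equal-length sequences over {A, C, G, T, N,
-}, each carrying a population label and a collection year (metadata
live in a sidecar TSV, keeping the FASTA standard-clean). Positions
are 1-based on the alignment coordinate system. Sites where either
member of a pair carries N or a gap are excluded for that pair
("pairwise deletion") in every pairwise computation. Haplotype
identity treats N as a wildcard by default — exact-duplicate sequences
are grouped first, then groups whose representatives are compatible
site-by-site are merged transitively — because sequencing ambiguity
otherwise inflates the haplotype count; `exact = TRUE` restores plain
string identity. With wildcard merging, compatibility is not a
transitive relation, so the transitive closure is taken; this is
order-independent and conservative (it can only reduce the haplotype
count further).

## Distances and diversity

Tamura–Nei (1993) distances use base frequencies averaged over each
sequence pair — the classic pairwise estimator; whole-alignment
frequencies are available via `freqs = "alignment"`. Gamma rate
heterogeneity (default shape 0.4, the value typical of control-region
data) replaces each `-k log w` term with `k·α(w^(-1/α) − 1)`. A pair
whose correction argument is non-positive is reported as a saturation
error naming the pair, rather than silently returning NaN.

Nucleotide diversity π and the mean pairwise difference k use *raw*
(uncorrected) differences. This is deliberate and visible in the
numbers such data sets report: mean differences divided by alignment
length equals π exactly only under the raw model, and that identity is
enforced by a unit-consistency test. Model-corrected distances are
used where the method calls for them (Φ_ST, trees). The standard
deviations of h and π are the Nei (1987) estimators (eqs. 8.12 and
10.7), the forms implemented by the field's standard software.

## Population structure

Φ-statistics come from the analysis of molecular variance on squared
molecular distances. For a pair of populations, Φ_ST is the
among-population fraction of molecular variance; its permutation null
shuffles individuals between the two samples, and p-values carry the
+1 correction so p = 0 cannot occur. The conventional permutation
count for a full study is 20100; the test suite uses smaller counts,
which changes resolution but not exactness of the permutation test.
The three-level decomposition (among groups Φ_CT, among populations
within groups Φ_SC, within populations) uses the classic
expected-mean-square coefficients; with one population per group the
middle level is empty and Φ_ST reduces exactly to the pairwise
statistic, which is tested. Negative Φ estimates are reported as
computed, but clamped to zero inside Slatkin linearisation
D = Φ/(1−Φ) and migrant conversion M = (1−Φ)/(2Φ), where a negative
value has no interpretation.

Temporal replicates of one location are pooled when no pairwise test
rejects; a replicate that differs is re-tested against the pooled
remainder and kept separate (flagged) if it still differs — the
pattern expected under "chaotic genetic patchiness", where a cohort
dominated by few families looks transiently distinct.

Isolation by distance correlates M = (1−Φ_ST)/(2Φ_ST) with
geographic distance; the permutation null jointly permutes rows and
columns of the geographic matrix. Pairs with Φ_ST ≤ 0 have no defined
migrant number and are excluded with a warning. The p-value is
two-sided on r; r² is reported.

## Mismatch distributions and expansion models

Both expected mismatch curves are computed from the coalescence-time
density of a pair of genes in mutational time units (τ = 2uT, with u
the per-sequence per-generation mutation rate), the number of
differences being Poisson-distributed given the coalescence time.

* **Sudden demographic expansion**: equilibrium at θ0, instantaneous
  growth to θ1 at time τ. The pair coalesces at rate 1/θ1 until τ and
  1/θ0 beyond; the resulting mixture has an incomplete-gamma closed
  form, evaluated in log space so θ0 = 0 and θ1 at the 99 999 cap are
  exact limits rather than overflow hazards. At τ = 0 the curve
  reduces to the equilibrium geometric; at θ0 = 0, θ1 → ∞ it is a pure
  Poisson with crest at τ. Both limits are tested.
* **Spatial (range) expansion**: at time τ a single deme of size θ
  expanded into an infinite island system of demes of size θ with
  scaled migration M = 2Nm. Looking backwards, a pair sampled in one
  deme either coalesces within the deme (rate 1/θ) or separates by
  migration (rate M/θ), after which it cannot coalesce until the
  ancestral phase. Large M makes separation immediate and the curve
  collapses onto the demographic model with θ1 → ∞ — the two fitters
  are checked against each other in that limit.

Fitting minimises the sum of squared deviations between observed and
expected mismatch *frequencies* over the observed difference classes
(the convention of the standard software), by L-BFGS-B from several
data-driven starts (crest position, mean pairwise differences), with a
Nelder–Mead fallback. θ1 and M are capped at 99 999; a fit pinned at
the cap is flagged as a boundary case, not an error — star-like
genealogies genuinely drive θ1 to the boundary. The goodness-of-fit
p-value and the 95% CI of τ come from a parametric bootstrap:
coalescent genealogies are simulated under the fitted parameters,
their mismatch histograms refitted, and the observed SSD compared with
the bootstrap SSD distribution (p = fraction of bootstrap SSD at least
as large). The bootstrap places Poisson mutation counts directly on
genealogy branches (infinite-sites), exactly as the field's standard
implementation does; observed data from finite-sites sources therefore
carry a small extra lack-of-fit from recurrent mutation, which is
visible as mildly conservative SSD p-values at high diversity.

Unit conversions use u = L × rate × generation-time (defaults: 648
sites, 3.6×10⁻⁸ substitutions/site/year, 2 years), so expansion time
is T = τ/(2u) generations and effective female numbers are
N = θ/(2u). The widely printed shorthand "T = 2μ/τ" is dimensionally
inconsistent; the package implements the standard identity τ = 2uT,
which is what reproduces the reference conversions (τ = 13.4 →
287.2 ky under the defaults). Note that with a per-year rate fixed,
calendar-year conversions are invariant to the generation time — only
the generation count changes.

## Fu's Fs

θ is estimated by the mean pairwise difference; S′ is the probability
under the Ewens sampling distribution of observing at least the
observed number of haplotypes, computed from unsigned Stirling numbers
of the first kind carried in log space (any practical n is exact to
double precision); Fs = ln(S′/(1−S′)). An independent
Chinese-restaurant-process recursion reproduces the Ewens distribution
in the tests without touching the Stirling route. The p-value is the
fraction of neutral constant-size coalescent simulations (infinite
sites, θ = θ̂) with Fs at or below the observed value. Monomorphic
samples (S′ = 1) are flagged rather than erroring.

## Isolation with migration

The two-population model: demes of equal scaled size θ = 2N_ef·u (per
sequence) split T coalescent units (N_ef generations) ago and exchange
migrants at scaled rate M = 2N_ef·m. The genealogy, augmented with
explicit migration events on its branches, is sampled jointly with
(θ, M, T) under uniform priors; sequence data enter through an HKY
pruning likelihood (C++ kernel on compressed site patterns) with
branch lengths t·θ/(2L) substitutions per site. κ defaults to an
empirical estimate from the alignment's transition/transversion
ratio; θ's prior maximum defaults to twice the Watterson estimate,
M and T to 10.

Proposal kernels:

* **lineage re-simulation** — detach the branch above a random
  non-root node and redraw its migration path and reattachment from
  the conditional structured-coalescent prior given the rest of the
  genealogy. Because per-pair and per-lineage rates factorise, the
  proposal density cancels the prior exactly and the Hastings ratio is
  the bare likelihood ratio. The rare case where the detached node
  sits above the remaining root is skipped (the guard is symmetric, so
  detailed balance is untouched);
* **node-time slides** within windows bounded by neighbouring nodes,
  adjacent migration events and the T boundary (uniform within the
  window, hence symmetric);
* **θ windows** (likelihood-only, since θ only scales branch lengths);
* **M Gibbs draws** from its truncated-Gamma full conditional given
  the migration count and lineage time below T;
* **T moves**: reflected windows with deterministic deme-path
  extension/truncation (a truncation that would delete migration
  events is rejected — the reverse move could not recreate them), plus
  occasional joint independence draws of T together with a fresh
  genealogy from the prior, which free the chain from the low-T trap
  where deme-inconsistent topologies block window moves.

With the likelihood switched off (`likelihood_off = TRUE`) the chain
must — and in the tests does — return the uniform priors, which
exercises every kernel's detailed balance at once. Point estimates are
the modes of binned marginal posteriors ("highest posterior
probability" grid values); TMRCA is summarised from root-age samples
and converted to years per-sample via N(θ) and the generation time.
Desk-scale defaults are 100 000 cycles with 10 000 burn-in; the
classic long-run setting for this analysis (5 000 000 cycles, 500 000
burn-in) is available through the configuration and is documented as
long-running. The divergence-time likelihood is often nearly flat for
low-divergence data — a known identifiability weakness of this model —
so credible intervals are reported alongside the modes rather than
asserting convergence of a point estimate.

## Trees

Neighbour-joining (via ape) on TN93(+Γ) distances; bootstrap support
resamples alignment columns, rebuilds each replicate tree and scores
the original internal bipartitions (ape::prop.clades); rooting is on a
user-named outgroup. Negative NJ branch lengths (non-additive input)
are transferred to adjacent edges and clamped, with a message. Clock
linearisation makes the tree ultrametric by averaging node-to-tip path
lengths below each node (constrained monotone), then converts heights
to ages with age = height/(rate/2): the cited 2.1%/Myr figure is a
*pairwise* divergence rate, so the per-lineage rate is half — the
output records this to prevent factor-of-two drift. The
population-level UPGMA tree uses average-linkage clustering
(stats::hclust) on Slatkin-linearised distances.

## The synthetic-data generator

The generator draws coalescent genealogies under four scenarios —
constant size, sudden expansion (time-rescaled piecewise-constant
rates; θ0 = 0 collapses remaining lineages in a star burst), a
finite-island structured coalescent with a merge at τ approximating
the continuum spatial-expansion model, and the two-deme
isolation-with-migration history — then evolves sequences down the
genealogy under finite-sites TN93/HKY with discrete-gamma site rates
(8 categories, shape 0.4) from an AT-rich control-region-like base
composition (A 0.32, C 0.21, G 0.14, T 0.33). Default transition
multipliers (κ₁ = 16 for purines, κ₂ = 12 for pyrimidines) give an
overall transition/transversion ratio near 6, matching the strong
transition bias such data show. Optional adjacent-site hotspots
substitute two neighbouring positions in one event, reproducing the
co-segregating "doublet" signature. Above M = 200 the structured
simulator switches to the strong-migration limit (lineages well mixed;
pairwise coalescence rate 1/n_demes), the only tractable — and there,
accurate — regime.

`make_study_like_dataset()` emits the demo design: temporal-replicate
samples (n 20–49) from five coastal locations, all drawn from one
shared expansion genealogy (τ = 12, θ0 = 2, θ1 = 300, giving h ≈
0.99–1.0 and π ≈ 0.02 with between-location divergence equal to
within-location diversity, i.e. near-panmixia), plus one "odd"
replicate whose 26 sequences descend through a shallow low-diversity
coalescent (τ = 5, θ0 = 0, θ1 = 60; π ≈ 0.007) from a founder
sequence drawn from the same genealogy — a sweepstakes cohort that the
temporal-pooling stage should flag, not merge. What passing tests on
these data do **not** show: real control regions have indels,
heteroplasmy, sequencing error and mutation-model misspecification
that no finite-sites simulation reproduces; the generator validates
the statistics' logic, not any particular biological conclusion.

## Problem sizes and numerical choices

The test suite runs entire studies at reduced scale, chosen as the
smallest sizes at which each property is still sharply testable:
permutation calibration uses 500 panmictic replicates of n = 20 with
199 permutations (the permutation test is exact at any count);
bootstrap-CI coverage uses 100 data sets of n = 50 with 200 bootstrap
replicates; the isolation-with-migration study uses 30 replicates of
10 sequences per deme at 100 000 cycles. Tolerances follow the
quantity's own Monte-Carlo error at those sizes. Expected mismatch
curves are validated to sum to one within 1e-6 over their support;
AMOVA sums of squares must decompose to 1e-9; Fu's Fs agrees with
brute-force enumeration to 1e-9 for all cases to n = 8.

## Known limitations

Single-locus, maternally inherited inference: every parameter here is
a female effective quantity, and a single realisation of the
coalescent — the reason CIs are wide and should be reported. The
spatial-expansion simulator approximates the continuum model by a
finite island system. The IM sampler's divergence time mixes slowly
when data are weakly informative (reported via effective sample
sizes). Mantel tests with few populations have a degenerate
permutation null and are warned about. None of the methods model
recombination, selection or sequencing error (beyond N-ambiguity
handling).
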