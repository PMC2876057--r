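Package: phylodem
Title: Phylogeography and Historical Demography from mtDNA Control-Region Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intraspecific phylogeography and historical demography of
    maternally inherited sequence data, built around the analyses routinely
    applied to mtDNA control-region alignments of marine fishes: haplotype and
    nucleotide diversity, Tamura-Nei (1993) distances with gamma rate
    heterogeneity, Phi-statistics and hierarchical AMOVA with permutation
    nulls, temporal-replicate pooling, Slatkin-linearised F_ST with UPGMA
    clustering, Mantel tests of isolation by distance, mismatch distributions
    with sudden-demographic and spatial (infinite-island) expansion fits and
    parametric-bootstrap goodness of fit, Fu's Fs neutrality test, molecular
    clock unit conversions, neighbour-joining trees with bootstrap support and
    clock linearisation, and a two-population isolation-with-migration
    coalescent MCMC under an HKY finite-sites likelihood. A self-contained
    structured-coalescent simulator generates study-like synthetic data sets
    under constant-size, sudden-expansion, spatial-expansion and
    isolation-with-migration scenarios for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
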