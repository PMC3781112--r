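Package: flockpopgen
Title: Population-Genetic Analysis of Species Flocks from Dominant Markers and mtDNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing recently diverged species flocks with dominant
    binary markers (AFLP-style presence/absence matrices) and mitochondrial
    control-region sequences. Provides neighbor-joining trees with locus
    bootstrapping and tree-based hybridization diagnostics (leaf stability,
    lineage movement, homoplasy-excess removal experiments), haplotype
    collapsing and median-joining networks, sudden-expansion mismatch
    distribution fitting with parametric-bootstrap goodness of fit, pairwise
    F-statistics and hierarchical AMOVA with permutation tests, FST outlier
    scans (island-model simulation and a Bayesian locus-effect model),
    model-based admixture clustering with Evanno's delta-K and
    immigrant-ancestry tests, and a coalescent simulator of whole species
    flocks with known ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
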