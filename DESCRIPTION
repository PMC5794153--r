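Package: aflpsgs
Title: Dominant-Marker Population Genetics and Fine-Scale Spatial Genetic Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of dominant (band presence/absence) marker data such as
    AFLP: Bayesian estimation of null-allele frequencies with a non-uniform
    (Zhivotovsky-style) prior, Nei gene diversity and distances, analysis of
    molecular variance (AMOVA) with permutation tests, Wright's Fst with a
    permutation G-test, Mantel tests for isolation by distance, and fine-scale
    spatial genetic structure: pairwise kinship coefficients for dominant
    phenotypes under an assumed inbreeding coefficient, distance-class
    correlograms with permutation envelopes, the Sp statistic, Wright's
    neighbourhood size and gene-dispersal distances under census and reduced
    effective densities. Includes seeded simulators (island-model divergence
    and a spatially explicit isolation-by-distance forward model) so every
    estimator is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere,
    vegan,
    jsonlite,
    yaml
Config/testthat/edition: 3
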