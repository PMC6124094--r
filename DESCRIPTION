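Package: mtskyline
Title: Demographic History from Whole Mitochondrial Genomes via Extended
    Bayesian Skyline Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coalescent-based inference of piecewise-linear effective
    population size trajectories from whole-mtDNA alignments, in the style of
    extended Bayesian skyline plots: a coalescent simulator under
    piecewise-linear demographies with a partitioned TN93+I+G sequence
    simulator, a change-point skyline MCMC conditioned on a point genealogy,
    MCMC diagnostics (effective sample size, highest posterior density
    intervals), a log-scale profile-similarity statistic between demographic
    trajectories, the Hudson Fst estimator combined across loci as a ratio of
    averages, neighbour-joining clustering of either distance matrix, and a
    Mantel-test association between profile similarity and Fst.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
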