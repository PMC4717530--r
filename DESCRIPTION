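Package: phyloniche
Title: Phyloclimatic Analysis of Macroecological Niche Evolution
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for phyloclimatic analysis of niche evolution
    in species clades: fuzzy C-means clustering of georeferenced occurrence
    records into macroecological niches with a seven-index validity sweep,
    principal component ordination with rank-based group tests, simplified
    maximum-entropy niche models with bootstrap AUC evaluation, max-SSS
    thresholding and predicted niche occupancy (PNO) profiles, majority-rule
    tip-state coding, Bayesian Mk-model ancestral niche reconstruction with
    an exponential hyperprior MCMC and Bayes-factor tests of transition
    asymmetry, transition counting and timing on a dated chronogram, and
    Blomberg's K phylogenetic-signal tests over tree ensembles. Includes a
    seeded synthetic-data generator (environmental grids, occurrence clouds,
    dated trees, simulated discrete characters) so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    picante,
    phangorn,
    withr,
    Matrix
Config/testthat/edition: 3
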