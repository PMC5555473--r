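Package: ssbreg
Title: Single-Step Genomic Prediction for Populations Under Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and single-step Bayesian regression machinery for
    studying the accuracy and bias of genomic prediction in populations
    undergoing truncation selection. Provides a gene-dropping breeding
    population simulator (linkage-disequilibrium-bearing base population,
    random-mating expansion, mass sire selection), sparse numerator
    relationship matrix algebra for imputing marker covariates of
    nongenotyped individuals, a single-step marker effects model with all
    centering and genotypic-mean (J covariate) variants, a pedigree BLUP
    baseline, and an evaluation layer that summarises prediction accuracy
    and bias over replicated scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
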