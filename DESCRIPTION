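Package: fcselect
Title: Sparse Functional-Connectivity Biomarker Selection and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds diagnostic biomarkers from resting-state functional
    connectivity. Converts region-of-interest time series into Pearson
    connectivity vectors (band-pass filtering, nuisance regression, motion
    scrubbing), selects a small diagnosis-specific connectivity subset with
    L1-regularized sparse canonical correlation analysis under a diagnostic
    canonical constraint that factors out nuisance variables (site, age,
    sex, eye condition, medication), and trains a sparse logistic regression
    classifier with automatic relevance determination inside a 9x9 nested
    feature-selection and leave-one-out cross-validation protocol. Includes
    seeded synthetic-cohort generators with planted diagnosis and nuisance
    effects, classifier evaluation (diagnostic odds ratio, ROC AUC, exact
    binomial and permutation tests, Kolmogorov-Smirnov comparisons with
    Benjamini-Hochberg correction), and characterization statistics for an
    identified connectivity set (laterality, network enrichment,
    under/over-connectivity, distance analyses, clinical-score prediction
    with a bootstrap null).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    signal,
    stats,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
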