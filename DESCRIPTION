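Package: symptomnet
Title: Regularized Partial Correlation Networks for Ordinal Symptom Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimation and inference for Gaussian graphical models of ordinal
    psychopathology survey items. Fits sparse partial correlation networks by
    graphical lasso over a penalty path with extended-BIC (EBIC) model
    selection on Spearman correlations, and provides node expected influence,
    bridge expected influence, nodewise predictability, nonparametric
    bootstrap accuracy and case-dropping stability (CS coefficient),
    a permutation network comparison test for two groups with Holm-corrected
    per-edge tests, walktrap community detection (exploratory graph analysis),
    survey preprocessing (scale scoring, caseness, stressor recoding,
    Cronbach's alpha, odds ratios), and a synthetic-data generator that
    samples ordinal items from known sparse graphical models for
    recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    igraph,
    jsonlite,
    MASS,
    Matrix,
    mclust,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
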