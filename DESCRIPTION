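Package: brainpad
Title: Brain Age Prediction and Brain-PAD Statistics from Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating brain age from resting-state
    functional connectivity and testing for accelerated brain aging in clinical
    groups. Builds Pearson connectivity matrices from regional BOLD time series,
    vectorizes the upper triangle into edge features, removes imaging-site
    effects by per-subject Z-scoring or empirical-Bayes location/scale
    (ComBat-style) harmonization, fits a stacked ensemble of elastic net, ridge
    and Bayesian ridge regressions with five-fold out-of-fold predictions,
    applies a hold-out age-bias correction, and derives brain-predicted age
    difference (brain-PAD) scores together with the group-level statistical
    battery (Gaussian GLM with age and age-squared terms, Welch tests with
    Cohen's d, FDR correction, Spearman correlations, median splits). Includes
    a multi-site synthetic cohort generator with known edgewise aging structure
    so every stage is testable without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
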