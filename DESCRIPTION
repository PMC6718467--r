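Package: restreward
Title: Predicting Ventral Striatal Reward Activation from Resting-State
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for predicting ventral-striatum
    (VS) reward-anticipation measures from resting-state functional
    connectivity. Provides a seeded synthetic-cohort generator (block-structured
    resting covariance with subject-level network-coupling variation, monetary
    incentive delay task designs, recorded ground truth), first-level GLM
    fitting with canonical double-gamma HRF convolution and gain-anticipation
    contrasts, a rank-slope reward-sensitivity model, functional-connectivity
    estimation with combined motion/tissue-PC/bandpass nuisance regression and
    sign-flip max-statistic group inference, relevance vector regression
    implemented from the sparse-Bayesian evidence-maximisation updates,
    cross-validated prediction with scaling correction and permutation
    significance, and network-level decomposition of edge-space model weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
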