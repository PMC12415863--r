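Package: anesdose
Title: Neural-Network Dose-Response Models for Fish Anesthesia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-input feed-forward (1-H-1) neural network models of fish
    anesthetic dose-response, built around nutmeg-oil anesthesia in common
    carp, Danube sturgeon and rainbow trout. Provides the forward-pass engine
    with the linear, hyperbolic-tangent and logistic-sigmoid transfer
    functions (including the printed two-scaled logistic dialect), from-scratch
    implementations of adaptive-learning-rate gradient descent, resilient
    backpropagation and sequential incremental training, RMSE/MAPE/R-squared
    model evaluation with MAPE accuracy bands, a packaged zoo of eighteen
    published trained networks (three species by six endpoints), a calibrated
    synthetic dose-response generator, and an end-to-end pipeline for
    normalization, stratified train/test splitting, architecture search,
    performance reporting and welfare-limited dose recommendation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tibble,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
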