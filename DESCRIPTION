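Package: sadirt
Title: State-Aware Deep Item Response Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the State-Aware Deep Item Response Theory (SAD-IRT) model: a
    one-parameter logistic item-response model in which a per-trial latent
    state parameter, interpretable as relative subjective difficulty, is
    regressed from a time series of behavioural features recorded while a
    respondent works on an item. Student ability and item difficulty are
    produced by small index-input neural networks (Deep-IRT), the state is
    produced by a causal dilated temporal convolutional network with a
    standardize-and-weight output stage, and all components are trained
    jointly by minimizing cross-entropy with an adaptive-moment optimizer.
    The package also provides the baseline model family (Deep-IRT with and
    without batch normalization, scalar-parameter IRT, a summary-statistics
    feature baseline), a stratified cross-validation and early-prediction
    evaluation protocol, parameter-similarity and prediction-agreement
    reports, per-student AR(1) state analysis, and a seeded synthetic-data
    generator with known ground truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    data.table
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
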