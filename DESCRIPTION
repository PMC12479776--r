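Package: effortmet
Title: Modelling and Metabolite-Based Prediction of Effort-Based Motivation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, inversion and validation of a seven-parameter softmax
    choice model for incentivized mental and physical effort decisions
    (reward/punishment sensitivities, effort sensitivities, physical fatigue and
    mental learning dynamics, high-effort bias), together with a
    metabolite-to-behaviour prediction pipeline: two-stage feature selection,
    leave-one-out-tuned gradient-boosted regression, label-permutation null
    testing, Shapley attribution and linear-versus-quadratic (inverted-U) model
    comparison. A synthetic-cohort generator reproduces the statistical
    structure of a 7T MRS effort study (metabolite inter-correlations,
    plasma-brain links, planted metabolite-behaviour associations) so every
    stage runs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lhs,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
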