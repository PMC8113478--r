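Package: nncme
Title: Neural-Network Chemical Master Equations for Delayed Stochastic Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Approximates non-Markovian (delay) chemical master equations of
    transcription models by time-inhomogeneous Markovian master equations whose
    removal propensities are the outputs of a small neural network trained on
    snapshot histograms. Provides an exact delay stochastic simulation
    algorithm, finite state projection (FSP) transient and steady-state
    solvers, closed-form reference distributions for constitutive and bursty
    transcription with deterministic removal delay, transient, steady-state
    and partial-data training modes, and joint inference of kinetic parameters
    with profile-likelihood confidence intervals.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
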