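Package: lovedyn
Title: Continuous-Time Dynamics of Felt and Expressed Love in Daily Life
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hierarchical Bayesian modelling of momentary felt and expressed
    love measured by ecological momentary assessment (EMA). Fits a bivariate
    Ornstein-Uhlenbeck (continuous-time state-space) model to irregularly
    timed 0-100 self-reports via an exact continuous-discrete Kalman filter,
    estimates person-specific drift matrices (inertia and cross-influences)
    with group-level random effects, derives lag curves and peak cross-lag
    summaries from the drift matrix exponential, and relates person-specific
    dynamics to trait measures through default Bayes-factor correlation
    tests and exact correlation power analysis. Includes a synthetic-cohort
    generator emulating a 28-day, up-to-6-prompts-per-day EMA design for
    end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
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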