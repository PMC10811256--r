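Package: dyadpred
Title: Data-Driven Prediction of Psychotherapy Outcome and Alliance in
    Nested Dyadic Studies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for predicting psychotherapy treatment outcome and
    therapeutic alliance from baseline therapist and client
    characteristics in dyadic studies with clients nested in therapists.
    Implements a fast maximum-likelihood engine for two-level linear
    mixed models with a therapist random intercept, best-subset model
    search over linear, quadratic and pairwise-interaction terms (up to
    a configurable term cap) scored by AIC with a leave-one-client-out
    cross-validation overfitting guard, two-stage derivation of
    client-level targets (outcome slopes, between-client alliance
    aggregates, within-client alliance slopes) from longitudinal
    session records, Nakagawa-Schielzeth marginal R-squared, k-nearest
    neighbour imputation, residual diagnostics, effect grids for
    interpreting quadratic and interaction effects, and a calibrated
    synthetic dyadic-study generator with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    lme4,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
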