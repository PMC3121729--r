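Package: mprqr
Title: Quantile Regression Analysis of Medication Adherence Disparities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying disparities in medication adherence measured by
    the medication possession ratio (MPR). Computes per-patient MPR from
    pharmacy refill records using fixed-length refill windows with an
    eligible-day denominator and a 100% cap; fits conditional-quantile
    regression by smoothed check-loss minimization with a Newton solver and an
    exact small-instance oracle, alongside ordinary least squares and a
    random-intercept linear mixed model; maps clinically meaningful MPR
    cutoffs to quantile levels through the empirical CDF; provides xy-pair
    bootstrap percentile inference, a patient-level resampling comparison
    study, and a synthetic-cohort generator with a user-controlled conditional
    quantile structure so that quantile-varying covariate effects can be
    planted and recovered.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    lme4,
    lmtest,
    nortest
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
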