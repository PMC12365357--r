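Package: jmcure
Title: Bayesian Joint Models with Location-Scale Longitudinal and Mixture-Cure
    Interval-Censored Survival Submodels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits Bayesian joint models that couple a nonlinear mixed-effects
    location-scale longitudinal submodel (three-parameter logistic trajectory
    with subject-specific residual variance) to a Weibull mixture-cure survival
    submodel for interval-censored event times, linked through the
    subject-specific longitudinal mean and variance. Includes a scenario
    simulator, a bias/coverage simulation-study harness, goodness-of-fit
    residuals (IWRES, Cox-Snell under interval censoring and cure), and model
    comparison via Pareto-smoothed importance-sampling leave-one-out
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    survival,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
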