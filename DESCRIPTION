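Package: c14growth
Title: Bayesian Growth Models for the Time-Frequency of Radiocarbon Dates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits and compares bounded demographic growth models to the
    time-frequency of radiocarbon dates within a hierarchical Bayesian
    framework. Growth models (exponential, double-exponential with a
    changepoint, and exponential-logistic) are expressed as discrete
    probability mass functions over calendar years, coupled to observed
    radiocarbon ages through the calibration curve and Gaussian measurement
    error, and fitted by adaptive Metropolis-Hastings MCMC with exact
    discrete Gibbs updates of the latent calendar dates. Includes
    calibration-curve handling, date calibration and back-calibration,
    summed probability distributions (SPD), highest posterior density
    intervals and convergence diagnostics, WAIC-based model comparison,
    posterior-predictive SPD checks, and a simulation workbench for
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    coda,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
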