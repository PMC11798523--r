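Package: hanami
Title: Bayesian State-Space Estimation of Cherry Flowering Phenology Dates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates latent ("true") dates of cherry flowering phenophases
    (first flowering, first full bloom, last full bloom, last flowering) across
    a century from coarse air-temperature predictors and sparse, noisy
    observation records. Fits time-varying-coefficient regression models in
    state-space form, with intercept and temperature coefficients evolving as
    Gaussian random walks, by a forward-filter backward-sampling Gibbs sampler;
    an exact Kalman smoother is provided for the fixed-variance case. Includes
    readers for daily temperature and phenology observation tables, per-year
    temperature-window predictors (winter daily minimum, March mean, early
    April mean), a synthetic-data generator emulating century-long records with
    late-onset observation coverage, and downstream trend, credible-interval
    coverage, and station-comparison analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
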