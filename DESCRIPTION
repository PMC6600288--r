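Package: bosspls
Title: Bootstrapping Soft Shrinkage Variable Selection for NIR
    Calibration of Oil Adulteration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies adulteration of extra virgin olive oil from
    near-infrared spectra. Simulates FT-NIR transmission spectra of
    oil mixtures with realistic scatter and baseline artifacts,
    normalizes them with the standard normal variate transform,
    selects informative wavenumbers with the bootstrapping soft
    shrinkage (BOSS) algorithm during partial least-squares (PLS)
    modeling, and evaluates the reduced calibration with RMSECV,
    RMSEP and the coefficient of determination. All user-facing
    functions take a spectra data frame first and return tibbles, so
    the pipeline composes with the pipe; fitted objects have tidy(),
    glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
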