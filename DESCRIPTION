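Package: beartrack
Title: Camera-Trap Habitat-Use and Nocturnality Analysis Along an
    Urban-Wildland Gradient
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing camera-trap monitoring of a large
    carnivore across an urban-rural-wild disturbance gradient:
    independence filtering of detections, solar day/night
    classification, monthly count and effort tables, buffer-weighted
    covariate extraction, zero-inflated negative-binomial mixed models
    with a site random intercept fitted by adaptive Gauss-Hermite
    quadrature, AICc multimodel comparison, nocturnality risk ratios
    with a permutation null and highest-density intervals, Moran's I
    residual diagnostics, and a synthetic-study generator that emulates
    the full sampling design for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    geosphere,
    glmmTMB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
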