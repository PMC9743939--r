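Package: wipab
Title: Wearable-Specific Indicators of Physical Activity Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives wearable-specific indicators of physical activity
    behaviour (WIPAB) from epoch-level wrist-acceleration (ENMO) series:
    valid-day screening, sleep masking, intensity classification, bout
    detection, intensity-distribution metrics (intensity gradient, MX),
    accumulation metrics (power-law exponent, proportion of time in long
    bouts, Gini index) and temporal-correlation/regularity metrics
    (detrended fluctuation analysis, 24-h autocorrelation, Lempel-Ziv
    complexity, sample entropy, symbolic dynamics).  Includes a synthetic
    cohort generator with planted effects, association models for insulin
    sensitivity (QUICKI) and HbA1c with chained-equation multiple
    imputation and Rubin pooling, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    MASS,
    nnet,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    arrow,
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
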