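Package: geograin
Title: Geostatistical Mapping of Grain Micronutrients and Dietary Supply
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for geostatistical surveillance of micronutrient
    concentrations (Ca, Fe, Se, Zn) in staple cereal grain. Provides robust
    empirical variogram estimation (Matheron, Cressie-Hawkins and Dowd
    estimators) on great-circle distances, weighted-least-squares fitting of
    exponential variogram models, ordinary point and block kriging with
    leave-one-out cross-validation and the median standardized-squared-
    prediction-error model-selection rule, median-unbiased back-transformation
    and kriging-variance masking, conversion of predicted concentrations into
    percent-of-EAR dietary supply surfaces, and spatial linear mixed models
    with Matern-correlated random effects for linking grain composition to
    human biomarkers and to soil and environmental covariates, including
    FDR-controlled forward covariate selection. A synthetic-survey generator
    with known ground truth supports testing every stage by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
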