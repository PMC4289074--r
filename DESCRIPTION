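Package: fireseasons
Title: Fire-Weather Season Delineation by Nonparametric Mode Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates fire-weather seasons from multi-year daily weather
    records by uniform-kernel nonparametric mode clustering of standardized
    fire-weather variables (relative humidity, air temperature, solar
    radiation, wind speed, soil moisture). Sweeps the kernel radius to
    generate candidate seasonal models, culls them with ANOVA R-squared,
    AIC, Pillai's trace and days-per-year screens, characterizes surviving
    models as calendar seasons, and selects a representative model. Builds
    a two-dimensional canonical discriminant "fire-weather plane" with
    quadratic discriminant classification and leave-one-out
    cross-validation, attributes fire records by ignition source to
    seasons, and provides a cumulative-rainfall-anomaly two-season
    reference model plus stability validation by random data partitioning.
    Includes a synthetic daily-weather and fire-record generator so the
    full pipeline is testable without station data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    lubridate,
    readr,
    generics,
    stats,
    e1071,
    MASS,
    mclust
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
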