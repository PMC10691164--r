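Package: migcues
Title: Microclimate Cues and Migratory Phenology of Partially Migratory Birds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how fine-scale environmental conditions shape the
    migratory timing and distance of partially migratory birds. Segments GPS
    trajectories into daily centroids, detects departure and return dates and
    classifies residents, extracts microclimate temperature and NDVI at bird
    locations with 500 m buffer statistics and a cool-microrefugium indicator,
    builds population-relative exposure indices from penalized regression
    smooths, estimates intra-class-correlation repeatability of migratory
    traits with parametric bootstrap confidence intervals, and relates timing
    to environmental covariates through AICc-ranked mixed-effects model sets
    with collinearity screening and spline correlogram diagnostics. Includes a
    seeded simulator of landscapes and tracks with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
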