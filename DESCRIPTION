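Package: cordsdm
Title: Ensemble Species Distribution Modeling and Climate Range-Shift Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for correlative species distribution
    modeling of presence-only taxa: occurrence curation and spatial thinning,
    predictor stack preparation with multicollinearity filtering,
    pseudoabsence ensemble modeling with boosted trees, random forests and
    regression models, ROC-gated ensembling, maximized-TSS binarization, and
    loss/stable/gain range-change and elevational-shift accounting between
    present and future climate scenarios. Includes a seeded virtual-species
    landscape simulator so the whole workflow is testable end-to-end without
    external raster downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    geosphere,
    ranger,
    xgboost,
    nnet,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
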