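Package: ricelwc
Title: Leaf Water Content Estimation from Canopy Hyperspectral Reflectance
    and Multi-Source Covariates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating rice leaf water content (LWC) from canopy
    hyperspectral reflectance coupled with physiological and micro-ecological
    covariates. Implements the crop water stress index (CWSI) chain with a
    non-water-stressed baseline fitted from well-watered plots, chlorophyll
    fluorescence parameters (Fv/Fm, Y(II)), classical water-sensitive
    vegetation indices, an exhaustive two-band normalized-difference index
    search against LWC, covariate screening with regression diagnostics
    (Pearson correlation, VIF, tolerance, Durbin-Watson), coupled
    spectral-physiological multiple linear regression with year-based
    validation, and a machine-learning benchmark (decision tree, random
    forest, k-nearest neighbours, gradient boosting) against multiple linear
    regression. Includes a synthetic field-campaign generator with known
    ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils,
    rpart,
    ranger,
    xgboost,
    caret,
    car
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    withr
Config/testthat/edition: 3
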