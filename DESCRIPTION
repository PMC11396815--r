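Package: smcfusion
Title: Soil Moisture Prediction from Fused UAV Multispectral and Thermal Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature construction and model evaluation for estimating soil
    moisture content (SMC) under a crop canopy from UAV-borne six-band
    multispectral reflectance and thermal-infrared rasters. Implements a
    seeded synthetic-scene generator for plot experiments, gravimetric SMC
    arithmetic, canopy masking and a 15-index vegetation-index catalog,
    gray-level co-occurrence matrix (GLCM) texture statistics with
    four-direction averaging and an exhaustive two-feature texture-index
    search, thermal-image calibration with four canopy/soil temperature
    indices, Pearson significance screening, and a train/validation
    evaluation matrix over XGBoost, random forest, and a genetic-algorithm
    initialized backpropagation network.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    xgboost,
    randomForest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
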