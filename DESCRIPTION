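Package: paddy
Title: Intra-Field Rice Yield Prediction from UAV Multispectral and Thermal
    Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested pipeline for predicting intra-field rice grain yield
    from co-registered multispectral and thermal rasters acquired by
    unmanned aerial vehicles.  Includes a synthetic field simulator
    (spatially autocorrelated yield on a 50 cm grid, growth-stage-dependent
    reflectance, combine-harvester label artifacts), the six standard
    vegetation indices (CIgreen, GNDVI, NAVI, NDVI, RENDVI, TGI), raster
    aggregation and 5x5-pixel tiling with spatially blocked four-fold
    partitioning, five competing predictive models (null, linear, gradient
    boosted trees, and 2D/3D convolutional autoencoders trained by a
    built-in single-precision backpropagation engine), evaluation metrics
    (RMSE, R2, MAE, MBE), field-scale prediction maps, and feature-blanking
    importance analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    xgboost,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
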