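Package: wheatlai
Title: Winter Wheat Leaf Area Index Estimation from UAV Multispectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates winter wheat leaf area index (LAI) at the jointing stage
    from UAV multispectral imagery by fusing spectral vegetation indices, gray
    level co-occurrence matrix (GLCM) texture indices and canopy plant height
    derived from digital surface model differencing. Provides a synthetic UAV
    scene generator for end-to-end verification, Pearson correlation screening
    of candidate features, SPXY (joint x-y distance) calibration/validation
    partitioning, a six-algorithm regression suite (random forest, XGBoost,
    support vector regression, back-propagation neural network, 1-D
    convolutional network and LSTM) evaluated with R2, RMSE and RPD, random
    forest wheat-pixel masking scored by overall accuracy and Cohen's kappa,
    and per-pixel LAI inversion maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    randomForest,
    xgboost,
    e1071,
    nnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
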