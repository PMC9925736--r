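Package: porcimetry
Title: Point-Cloud Morphometry and Neural Weight Prediction for Growing Pigs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated pig morphometry and body-weight prediction from
    multi-view depth-camera point clouds. Provides a synthetic scene
    generator with known ground truth (lofted-superellipse pig bodies,
    pen floor, railings, sparse noise, three-camera rig with a reference
    calibration cuboid), rigid multi-view registration calibrated from
    cuboid face planes, scene filtering (pass-through crop, RANSAC floor
    removal, radius outlier removal), body-size measurement (dorsal-ridge
    length, withers height, abdominal width and circumference via a
    periodic cubic B-spline in polar coordinates), a tabular feature
    pipeline (cleaning, one-hot encoding, median imputation, row
    normalization, variance-threshold selection) and multilayer-perceptron
    regression of body weight with Adam-trained 5-4-4 networks and
    MSE/RMSE/MAE/MAPE evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
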