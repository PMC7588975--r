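Package: roifit
Title: Implicit Shape Approximation of Regions of Interest in Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits implicit shape equations (2D ellipses and 3D cashew-shaped
    quartic surfaces) to region-of-interest boundary points extracted from
    grayscale medical images, by minimising the total Euclidean
    point-to-surface distance with a particle swarm optimiser. Each distance
    is computed by a flashlight-searching algorithm that projects tangent
    plane probes back onto the surface along rays from the query point. The
    fitted coefficients serve as shape features for classification, and the
    package provides the accompanying evaluation protocol (stratified
    hold-out, 5-fold cross-validated classifier selection, repeated-round
    summaries and paired tests) together with a synthetic phantom and cohort
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    e1071,
    randomForest,
    xgboost,
    EBImage,
    png,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
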