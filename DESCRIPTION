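Package: rotometry
Title: Shoulder Rotation Angle Estimation from 2D Pose Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates shoulder internal/external rotation angles from the
    2D body landmarks emitted by 33-keypoint pose estimators. Provides
    readers and writers for per-frame landmark tables, a forward-kinematic
    simulator that renders a standing subject with a 90-degree flexed elbow
    through an orthographic or pinhole camera, seven trunk-normalized
    geometric features (signed parallelogram areas, segment-length ratios
    and joint angles), five regression models of the rotation angle, and an
    evaluation battery covering correlation, mean absolute error, per-angle
    residual summaries, tree feature importance and Shapley additive
    attributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Rcpp,
    data.table,
    e1071,
    glmnet,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
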