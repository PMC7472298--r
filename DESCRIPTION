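Package: swingseg
Title: Golf Swing Phase Segmentation from a Single Body-Worn IMU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments a full golf swing recorded by a single six-axis inertial
    measurement unit (IMU) into its five phases (before-swing, backswing,
    downswing, follow-through, after-swing) by estimating the four dividing
    points: address, backswing top, impact and finish. Implements three
    estimators: a rule-based heuristic using signal extrema and zero
    crossings, a bidirectional LSTM per-timestep phase classifier, and a 1-D
    convolutional network that regresses the four event times directly, with
    zero-phase Butterworth preprocessing, impact-centred windowing,
    leave-one-subject-out evaluation, and a calibrated synthetic
    swing-kinematics generator for training and verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
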