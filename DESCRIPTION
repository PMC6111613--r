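Package: orientHAR
Title: Orientation-Invariant Activity Recognition from Wearable Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pre-processing and evaluation pipeline for human activity
    recognition with body-worn inertial measurement units (tri-axial
    accelerometer, gyroscope and magnetometer) that is robust to the
    orientation at which each sensor unit is attached to the body. Estimates
    per-sample sensor orientation with a complementary quaternion filter
    (gyroscope integration fused with a Gauss-Newton accelerometer and
    magnetometer correction), re-expresses the sensor streams in the
    North-East-Down Earth frame, and encodes the rotation between consecutive
    samples as differential quaternions in the Earth frame. Includes five
    comparison transforms (none, random rotation, Euclidean norm, gravity
    decomposition, SVD axes), windowed statistical feature extraction, PCA,
    seven classifiers (SVM, neural network, Gaussian and linear discriminant,
    k-NN, random forest, sparse-representation via orthogonal matching
    pursuit), leave-one-subject-out evaluation, and a synthetic IMU generator
    with ground-truth orientation trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    randomForest,
    class,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
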