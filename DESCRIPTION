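Package: stepdir
Title: Foot Stepping-Direction Identification from a Foot-Mounted IMU
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Real-time identification of foot stepping motions (jump, step
    left, step right, step forward, step backward) from a shoe-mounted
    six-axis inertial measurement unit. Provides deterministic sensor-error
    compensation (bias, scale factor, non-orthogonality), an error-state
    Kalman attitude filter with adaptive measurement-noise tuning that fuses
    gyroscope integration with accelerometer gravity residuals, projection of
    measurements into a Right-Forward-Up user frame that cancels mounting
    misalignment, push-off peak-triggered gait segmentation into fixed
    31-sample windows, time-domain feature extraction (mean, variance, signal
    magnitude area, short-horizon position change, and strength-invariant
    axis ratios), a one-vs-rest bank of per-motion binary classifiers
    (decision tree, k-nearest neighbours, support vector machine), confusion
    metrics with 10-fold and holdout cross-validation, and a seeded synthetic
    gait-IMU generator for end-to-end testing without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    rpart,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
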