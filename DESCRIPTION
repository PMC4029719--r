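Package: promyo
Title: Proportional Myoelectric Control of a Pneumatic-Muscle Elbow Joint
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating a proportional myoelectric
    control loop for an antagonistic pneumatic-muscle elbow joint: a seeded
    generator of synthetic four-channel surface-EMG and elbow-angle trials,
    the causal Butterworth/rectify/low-pass conditioning chain with
    overlapped-window RMS feature extraction, a from-scratch 4-3-1 sigmoid
    back-propagation network mapping muscle RMS features to elbow angle, a
    McKibben pneumatic-muscle force model with antagonistic-pair
    differential-pressure inversion, a thresholded streaming control loop,
    and the standard prediction-quality statistics (RMSE, R-squared,
    regression slope and intercept).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
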