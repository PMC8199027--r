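Package: hyoidtrack
Title: Hyoid Bone Tracking in Synthetic Ultrasound Swallowing Videos
Version: 0.1.0
Authors@R: person("USV", "Tracking Project", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to study automatic hyoid bone tracking in B-mode
    ultrasound swallowing videos. Provides a seeded synthetic video
    generator that emulates the geometry and speckle statistics of
    submental ultrasound recordings with exact ground-truth hyoid
    trajectories, a from-scratch fully-convolutional Siamese tracker
    (offline-trained score-map matching with a padding-free AlexNet-style
    backbone), a Fourier-domain discriminative correlation filter
    baseline, and the full kinematic evaluation suite used for swallowing
    studies (center error, one-pass-evaluation precision curves, RMSE,
    average error, per-axis Pearson correlation, and range-of-motion
    relative error), together with file formats and a command-line
    interface chaining simulation, training, tracking, and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
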