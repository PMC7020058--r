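Package: bitewise
Title: Automatic Bite Detection and Meal Microstructure Analysis from
    Pose Keypoints
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects eating events (bites) in videotaped meals from
    per-frame body and mouth pose keypoints, and derives meal
    microstructure analytics.  Provides a synthetic meal-keypoint
    generator, OpenPose-style keypoint and annotation I/O, keypoint
    cleaning/smoothing/normalisation into two feature streams, a
    two-stream convolutional + LSTM bite classifier with sliding-window
    inference and probability-signal peak extraction, per-meal summaries
    (duration, bites, per-10%-segment rates, quadratic meal-progress
    fits), and inter-rater agreement statistics (Cohen's kappa, recall,
    specificity, F1 variants, event matching, Pearson correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
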