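Package: pupilkit
Title: Pupillometry with a Compact Encoder-Decoder Pupil Segmentation Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trainable and testable toolkit for camera-based pupillometry in
    mice and humans. Provides a compact "hourglass" encoder-decoder
    convolutional network (constant width, 16 3x3 kernels per layer) that
    jointly predicts a per-pixel pupil probability map and scalar eye/blink
    probabilities; its full training recipe (augmentation, summed binary
    cross-entropy loss, AdaBelief optimizer, best-snapshot selection, Dice
    evaluation); a frame-to-measurement pipeline (ROI tracking, preprocessing,
    map thresholding, morphological refinement, CSV export); downstream
    time-series analysis (blink interpolation, z-scored event-related
    transients, locomotion states, pointwise FDR-corrected significance,
    cross-device trace agreement); a seeded synthetic eye-image and
    eye-video generator with exact ground truth; and a reader for annotated
    eye-image datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
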