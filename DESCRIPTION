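Package: gmascreen
Title: Automated General Movements Screening from Infant Pose Keypoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for automated screening of infant General Movements (GMs)
    from video-derived pose-estimation keypoints. Implements a geometry-aware
    preprocessing pipeline (confidence filtering, elliptical outlier removal,
    gap filling, camera-rotation alignment, infant-size scaling and framerate
    normalisation), a clip-attention neural classifier built from causal 1D
    convolutions with sigmoid attention pooling, probability calibration under
    class imbalance, canonical time-series feature baselines, grouped
    stratified cross-validation, gradient saliency analysis, and a synthetic
    supine-infant movement simulator for end-to-end testing without
    identifiable video data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    yaml,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
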