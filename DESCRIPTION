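Package: sitrack
Title: Surgical Instrument Tracking and Motion-Based Surgical Skill Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tracking-by-detection of surgical instruments in robotic-surgery
    video and quantitative assessment of surgical skill from instrument motion.
    Provides a SORT-style tracker (constant-velocity Kalman filter, IOU and
    appearance costs, Hungarian assignment) with a hard three-instrument cap, a
    cascaded re-identification stage (offline appearance gallery followed by an
    online bag-of-visual-words model trained on the previous ten frames),
    arm-indicator recognition by normalized cross-correlation template matching,
    instrument-tip localization with pixel-to-millimetre calibration from the
    known 8 mm shaft width, nine motion metrics (time to completion, instruments
    out of view, collisions, economy of motion, average speed, number of
    movements, economic factor, instrument changes, laparoscopy usage), and
    novice/skilled/expert classifiers (multinomial linear, Gaussian-kernel SVM,
    random forest) with SMOTE class balancing and five-fold cross-validated
    tuning. A synthetic surgical-scene simulator with complete ground truth
    makes every stage testable without real video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    EBImage,
    e1071,
    randomForest,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'sceneSim.R'
    'detection.R'
    'hungarian.R'
    'kalman.R'
    'tracker.R'
    'evaluation.R'
    'utils.R'
    'indicators.R'
    'metrics.R'
    'tips.R'
    'reid.R'
    'pipeline.R'
    'randomScene.R'
    'reidBenchmark.R'
    'sitrack-package.R'
    'skillCohort.R'
    'skillModel.R'
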