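Package: pillcam
Title: Medication-Taking Behavior Recognition from Wrist-Camera Object
    Detections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline for recognizing medication-taking
    behavior in short wrist-camera episodes. Stage one is a desk-scale
    region-based detector (connected-component region proposal, fixed-size
    warp/crop features, linear SVM region classification, bounding-box
    regression, non-maximum suppression) over nine medication-related
    object categories. Stage two converts per-frame detections into a
    "sequence of takes" feature stream and classifies episodes with an
    LSTM implemented from its gate recurrences, a rule-based
    pill-to-mouth recognizer, and four classical baselines. A synthetic
    episode generator with a step grammar, glyph renderer and detector
    noise model provides labeled data end to end, and evaluation modules
    compute IoU, per-category average precision at IoU 0.5, confusion
    matrices and model-comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    withr,
    e1071,
    xgboost,
    randomForest,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
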