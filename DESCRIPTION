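Package: somnokit
Title: Contactless Sleep-Pattern Monitoring from Pillow Pressure and Ambient Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for unconstrained, contactless sleep monitoring
    from 1 Hz multi-channel recordings: an eight-sensor pillow pressure array,
    sound pressure level, contactless body temperature, room climate, CO2 and
    an optional heart-rate reference. Provides sleeping-posture discrimination
    (centroid heuristic and support-vector classifier), toss-and-turn and
    snore event detection with interval-regularity statistics, heart-rate
    episode annotation, rule-based and tree-ensemble REM/NREM sleep staging
    with ROC/AUC evaluation against a heart-rate-derived reference, a seeded
    synthetic full-night session simulator with ground truth, and an
    end-to-end pipeline producing machine-readable night reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    e1071,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
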