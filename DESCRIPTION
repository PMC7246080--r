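Package: ctvshift
Title: Predicting Prostate Target Shifts from Sagittal Anatomical Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Semi-automated prediction of prostate clinical-target-volume
    (CTV) shifts between a planning CT and a pretreatment cone-beam CT.
    Geometric features of the bladder, rectum and prostate, measured on the
    isocenter sagittal plane relative to two pubic-bone landmarks, are fed
    to five regression learners (Levenberg-Marquardt, Bayesian-regularized
    and scaled-conjugate-gradient neural networks, epsilon-SVR with an
    IQR-based cost, and random forests), evaluated by leave-one-patient-out
    cross-validation and an independent validation protocol, and compared
    with intensity-based rigid registration by correlation ratio. A
    synthetic sagittal pelvic-anatomy simulator generates fully labelled
    cohorts so that every stage is testable without patient images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
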