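Package: smrfes
Title: Sensorimotor-Rhythm BCI Pipeline for Motor-Imagery Controlled
    Functional Electrical Stimulation
Version: 0.1.0
Authors@R:
    person("BCI", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a sensorimotor-rhythm (SMR)
    brain-computer-interface pipeline that drives functional electrical
    stimulation (FES) from two motor-imagery classes in a single hand.
    Provides a synthetic EEG generator with motor-imagery structure
    (mu/beta rhythms, event-related desynchronization, ocular and
    stimulation artifacts), the preprocessing chain (notch, artifact
    rejection, band-pass, PCA, ICA cleaning, surface Laplacian), sub-band
    ERD/ERS and common-spatial-pattern feature extraction, LDA and
    least-squares SVM classification with a weighted-majority ensemble,
    unsupervised pooled-mean classifier adaptation, a semi-asynchronous
    fixed-sequence control loop, and completion-rate / accuracy /
    information-transfer-rate reporting.  Sessions round-trip through
    EDF+ files with per-period annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
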