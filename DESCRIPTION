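Package: entotrap
Title: Optoacoustic Wingbeat Detection and Verification for Electronic Insect Traps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: A software twin of an optoacoustic electronic McPhail trap for
    monitoring the olive fruit fly (Bactrocera oleae). Provides a harmonic
    wingbeat simulator with species presets, RMS-threshold event detection on
    fixed 512-sample frames, Hamming-windowed FFT magnitude signatures with
    unit-L2 normalization, K-means prototype codebooks with a mean plus three
    standard deviation L1-distance acceptance threshold for open-set
    verification, two-codebook closed-set classification, precision/recall/F1
    evaluation with support-weighted averages, model-based cross-validation
    baselines, and an end-to-end trap runtime that emits telemetry payloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    randomForest,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
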