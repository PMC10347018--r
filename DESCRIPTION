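Package: pcglstf
Title: Long Short-Term Feature Extraction and Classification for Heart Sounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-timescale analysis of phonocardiogram (PCG) recordings for
    binary normal/abnormal screening. Segments the fundamental heart sounds
    (S1, S2) with a Shannon-energy envelope, threshold peak detection and an
    extra-peak-rejection rule set; extracts 27 short-term features (time,
    statistics, energy, frequency and 13 MFCCs) from five-second fragments
    and 6 long-term interval/rejection features from whole recordings; pools
    them into a 33-dimensional long short-term representation; ranks features
    by neighborhood component analysis; and compares classical classifier
    families (trees, naive Bayes, SVM, KNN, ensembles) across feature sets.
    Includes a synthetic PCG simulator with ground-truth S1/S2 annotations
    for end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    rpart,
    class,
    MASS,
    randomForest,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
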