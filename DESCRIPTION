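Package: embryostream
Title: Two-Stream Spatio-Temporal Prediction of Blastocyst Formation from
    Time-Lapse Embryo Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting blastocyst formation and usable-blastocyst
    quality from day-1 to day-3 time-lapse monitoring (TLM) videos of human
    embryos. Implements the video-preparation stage (1-cell recognition,
    pronuclear presence estimation, a run-length correction filter for noisy
    per-frame sequences, pronuclear-fading localization and video screening),
    per-frame cell-stage counting with a focal-loss classifier, a
    pronuclear-fading-anchored temporal stream over morphokinetic stage
    sequences, a spatial stream over frame embeddings at the five clinical
    observation checkpoints, and a weighted two-stream ensemble with a full
    evaluation suite (sensitivity, specificity, PPV, NPV, accuracy, ROC/AUC).
    Includes a synthetic embryo-video generator with per-frame ground truth so
    the complete pipeline can be trained and evaluated end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    nnet,
    xgboost,
    tiff,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
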