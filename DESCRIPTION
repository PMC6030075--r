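Package: notecast
Title: Short-Term Survival Prediction from Longitudinal Free-Text Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline that turns longitudinal free-text clinical
    visit notes into context-aware dense vectors and feeds each patient's
    visit-vector sequence to a stacked recurrent classifier that outputs, at
    every visit, the probability of surviving beyond three months. Stage one
    (intelligent word embedding) condenses note text (stopword removal,
    stemming, number and relative-date normalization, pointwise-mutual-
    information bigram collocations), maps surface terms to a controlled
    vocabulary, trains skip-gram word embeddings, and averages embedding
    vectors in fixed windows around controlled-term occurrences to form one
    vector per note. Stage two assembles per-patient visit sequences with
    per-visit three-class labels (survival-positive, survival-negative,
    padded), and trains a two-layer stacked LSTM with inter-layer batch
    normalization, dropout and a time-distributed weighted cross-entropy
    loss. Includes ROC/Brier/decile-calibration evaluation with patient-level
    bootstrap confidence intervals, per-stratum AUC, a per-patient
    explanation report with highlighted controlled-term contexts, and a
    synthetic-cohort generator with a plantable textual prognosis signal so
    the whole pipeline is testable without real medical records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    yaml,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
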