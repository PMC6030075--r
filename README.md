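# notecast

Short-term survival prediction from longitudinal free-text clinical notes.

## The problem

Physicians systematically over-estimate the short-term life expectancy of
patients with metastatic cancer, which can lead to overly aggressive
treatment near the end of life. The question a clinician actually faces at
every visit is: *will this patient survive beyond the next three months?*
Most of the evidence that bears on that question lives in free-text visit
notes — oncology notes, radiology reports, inpatient notes — accumulated
over an irregular visit history.

`notecast` implements a two-stage pipeline for this setting:

**Stage 1 — intelligent word embedding.** Raw notes are condensed
(stopword removal with clinical negations retained, Porter stemming,
number-to-word conversion, conversion of in-text dates to relative-gap
tokens like `three_month_ago`, PMI-selected bigram collocations merged into
single tokens), then a controlled-term dictionary (CLEVER-style two-column
TSV: surface form → controlled term, e.g. `no → NEGEX`,
`probable → RISK`) maps corpus terms sharing a root with dictionary
surfaces onto canonical controlled terms. Skip-gram word embeddings are
trained on the mapped corpus, and each note is summarized by a
context-aware vector: for each controlled-term occurrence *c*, the mean of
the embedding vectors in a window of the term ± `cwindow` tokens, averaged
over occurrences,

    v_note = (1/N) * Σ_{c ∈ CTerms} (1/n_c) * Σ_{w ∈ CWindow(c)} v_w

with the all-zeros vector for notes containing no controlled term.

**Stage 2 — recurrent survival classification.** Each patient's
time-ordered visit vectors x⁽¹⁾…x⁽ᵀ⁾ (zero-padded / truncated-to-recent at
a fixed length) feed a stacked unidirectional LSTM — 50 then 25 hidden
units with frame-wise batch normalization between layers and 10% dropout
before a time-distributed 3-class softmax over {survival-positive,
survival-negative, padded}. Training minimizes the time-distributed
weighted cross-entropy (weights 2 / 1 / 0.1 by true class; censored visits
weight 0) with Adam at learning rate 0.001 decayed 0.0001 per epoch. The
model is strictly causal: the probability emitted at visit *t* depends only
on visits 1…t.

The package also provides ROC/AUC with patient-level (cluster) bootstrap
confidence intervals, Youden best cut-off, Brier score, precision-recall
AUC, decile calibration tables, per-stratum AUC, a per-patient HTML
explanation report (survival-probability curve against ground truth, with
each visit expandable to its highlighted controlled-term findings), and a
synthetic-cohort generator with a plantable textual prognosis signal so
that every stage is testable without any real medical records.

## Worked example

```r
library(notecast)

# 1. a synthetic cohort with a planted terminal-phase textual signal
coh <- generate_cohort(cohort_config(n_patients = 200, signal_strength = 1,
                                     seed = 1))
cohort_stats(coh$notes, coh$outcomes)
#> cohort: 200 patients, 1656 visits
#> labels: POS 1301 | NEG 329 | UNDEFINED 26

# 2. condense, merge collocations, map to controlled terms
corpus <- condense_notes(coh$notes)
colloc <- fit_collocations(corpus, min_count = 25, top_k = 50)
mapped <- map_corpus(apply_collocations_corpus(corpus, colloc),
                     load_dictionary(example_dictionary_path()))

# 3. embeddings and context-aware note vectors
emb <- train_embeddings(mapped, dim = 32, window = 5, seed = 1)
vectors <- vectorize_corpus(mapped, emb, cwindow = 15)

# 4. sequences, training, prediction, evaluation
ds <- build_sequences(vectors, coh$notes, coh$outcomes, max_len = 20)
sp <- split_cohort(ds, c(0.7, 0.15, 0.15), seed = 1)
fit <- train_model(sp$train, sp$validation, model_config(D = 32, seed = 1))
pred <- predict_sequences(fit, sp$test)
evaluate_predictions(pred, n_boot = 200, seed = 1)
#> AUC 0.965 [0.919-0.992], best cutoff 0.525
#> Brier 0.1940 | PR-AUC 0.994 | 231 visits / 29 patients
```

The AUC close to 1 says the model recovered the planted fatal-signal
phrases from the notes of dying patients (at this small cohort size the
probabilities are less sharply calibrated than the ranking — larger
cohorts, as used in `scripts/acceptance.R`, bring the Brier score down to
about 0.02); with `signal_strength = 0` the held-out AUC drops to chance,
confirming the labels are otherwise unpredictable.

A per-patient explanation report (curve + highlighted controlled-term
contexts per visit) is written with:

```r
render_cohort_reports(pred, coh$notes,
                      load_dictionary(example_dictionary_path()),
                      patients = unique(pred$predictions$patient_id)[1:3],
                      out_dir = "reports")
```

## Command line

Every stage is also exposed as a subcommand of a thin Rscript:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "notecast.R", package = "notecast"))') \
    simulate --out-dir sim --seed 9 --n-patients 200
# then: condense, map-terms, embed-train, vectorize, build-dataset,
#       train, predict, evaluate, explain   (flag lists in the script header)
```

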