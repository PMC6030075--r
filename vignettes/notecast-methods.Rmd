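---
title: "Methods: survival prediction from longitudinal clinical notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survival prediction from longitudinal clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`notecast` estimates, at every clinical visit, the probability that a
patient survives beyond three months, using nothing but the free-text visit
notes accumulated up to that visit. This vignette is the package's account
of the model, its assumptions, the tunable parameters, what the synthetic
cohort does and does not emulate, and the numerical and design choices a
maintainer would want to know about.

## The two-stage model

### Stage 1: from raw text to a note vector

A raw note passes through the *condenser*:

1. **Relative-date conversion.** Every date mentioned in the text
   (ISO-8601, `MM/DD/YYYY`, or `Month D, YYYY`) is replaced by the bucketed
   gap to the visit date: `same_day`, `one_day_ago` … `six_day_ago`,
   `one_week_ago` … `four_week_ago` (up to 30 days), `one_month_ago` …
   `eleven_month_ago` (month = 30.44 days), then years (year = 365.25
   days), rounded half up; future dates use an `_ahead` suffix. The text of
   a note is only meaningful relative to when it was written — "scan of
   2015-03-01" carries the information "three months ago", and the bucket
   token makes that explicit and vocabulary-bounded. Unparseable date-like
   strings are left untouched.
2. **Tokenization.** Lowercase; split on anything that is not a letter,
   digit, hyphen or underscore.
3. **Number conversion.** Integers 0–20 become words; larger numbers
   collapse to magnitude tokens (`num_tens`, `num_hundreds`,
   `num_thousands`, `num_large`) so the vocabulary stays bounded.
4. **Stopword removal.** The built-in stoplist contains closed-class
   function words only (articles, determiners, pronouns, prepositions,
   conjunctions). Negations — *no, not, nor, never, without* — are
   deliberately *not* stopwords, because the controlled-term dictionary
   maps them (`no → NEGEX`) and negation is clinically decisive.
5. **Stemming.** The classic Porter algorithm, implemented in the package
   (no stemmer is otherwise available to it), shared by every stage that
   compares tokens. Porter stemming is not idempotent (`diffuse → diffus →
   diffu`), which is why the re-condense invariant is stated *modulo
   re-stemming*.

**Collocations.** Adjacent token pairs are scored by pointwise mutual
information, PMI(a,b) = log( c(a,b)·T / (c(a)·c(b)) ), with T the total
adjacent-pair count. Pairs below a count floor are discarded and the top-k
survivors are merged into single underscore-joined tokens. The reference
defaults are a floor of 50 and k = 1000; synthetic corpora are far smaller,
so the pipeline helper uses 25/50 by default while keeping 50/1000 on the
fitting function itself. Ties are broken by higher count, then
lexicographically, for reproducibility. Counting happens *after* stopword
removal and stemming (the alternative order would change counts; either is
defensible, one had to be fixed). Tokens already containing an underscore
(date buckets, earlier merges) are excluded as collocation candidates so a
merged token always contains exactly one join.

**Semantic dictionary mapping.** The dictionary is a two-column TSV of
surface form → controlled term. Two indexes are built: exact (tokenized
lowercase surface) and stemmed (the surface passed through the same
condenser rules, so multi-word phrases lose their stopwords exactly as the
notes do). Matching is longest-span-first (up to 6 condensed tokens),
exact-before-stem at each length. A matched span is replaced by its
uppercase controlled term; since note tokens are lowercase and matching is
case-sensitive, mapping is idempotent, and the loader rejects any
dictionary that would break that. Multi-word spans shorten the token
stream; the recorded (position, span) pairs keep the alignment recoverable.
Where both an exact and a stem entry could match a token, the exact surface
wins — the more specific evidence.

**Embeddings and the note vector.** Skip-gram with negative sampling is
trained on the mapped corpus (the trainer is compiled C++ with an internal
seeded RNG: single-threaded, deterministic by seed). Reference settings are
700 dimensions, window 30, minimum token count 5; tokens below the count
floor get no vector. The note vector averages, over every controlled-term
occurrence, the mean embedding of the occurrence's context window. Three
readings of the window were possible; the implemented one is: the term
itself plus up to `cwindow` (default 15) tokens on each side, truncated at
note boundaries, the term's own vector included. Out-of-vocabulary window
tokens are skipped and excluded from the denominator rather than
zero-imputed, which would bias contexts toward the origin. A note with no
controlled term (or no in-vocabulary context) gets the all-zeros vector —
which is also what makes zero-padding unambiguous downstream, so the
synthetic generator guarantees at least one dictionary surface form per
note.

### Stage 2: the recurrent classifier

Visits are ordered by date (ties by note id — several providers can see a
patient the same day, and each note is a separate timestep). Each visit is
labelled by date arithmetic against the outcome record: survival-negative
if death occurs within 91 days of the visit (91 ≈ 3 × 30.44, the package's
reading of "three months"), survival-positive if death or follow-up lies
beyond 91 days, and *undefined* when the patient is alive but follow-up
ends inside the horizon — the outcome is unknowable, the visit is censored.
Censored visits stay in the input sequence (dropping them would distort the
recurrent state) but carry zero loss weight and are excluded from all
evaluation. Sequences are truncated to the most recent `max_len` visits
(recent state is the relevant state for short-term survival) and
right-padded with zero vectors labelled PAD.

The network is: input (D) → LSTM(50, unidirectional, sequence output) →
frame-wise batch normalization → LSTM(25) → dropout(0.10) →
per-timestep dense + softmax over the three classes. Batch normalization
uses one set of statistics shared across timesteps (per-timestep statistics
would break causality at inference and make padding positions
distribution-shifting); inference uses running averages (momentum 0.99,
eps 1e-3). The loss is the mean over all sequence cells of the
cross-entropy against the true class, weighted 2 / 1 / 0.1 for
positive / negative / padded and 0 for censored. The published loss is
written in binary form yet the output is a three-class softmax; weighting
the categorical cross-entropy by the true class's weight is the only
reading consistent with the stated 2×/1×/0.1× scheme. Training is Adam
(lr 0.001, decayed as lr/(1 + 0.0001·epoch)), patient-shuffled batches
(seeded per epoch), global gradient-norm clipping at 5 (an addition — long
sequences make exploding gradients a practical risk), and checkpointing of
the best validation accuracy. "Stateful" recurrence across batches is not
reproduced: each padded sequence fits in one pass, so state is per-patient,
which is also the only well-defined reading once patients are shuffled.
Accuracy is logged both including padding (the over-optimistic bookkeeping)
and on real visits only.

Correctness of the hand-written backpropagation (through both LSTMs, batch
normalization in batch-statistics mode, dropout and the weighted loss) is
enforced by a finite-difference gradient check in the test suite, and
causality — bit-identical earlier outputs under any future-input
perturbation — is asserted directly.

## Evaluation

All metrics are computed on non-padded, non-censored visits. AUC uses the
rank (Mann–Whitney) formulation with tied scores counting ½ (the standard
convention; a choice that had to be fixed). The confidence interval is a
percentile bootstrap that resamples *patients*, not visits, because visits
within a patient are strongly dependent; a visit-level mode exists for
comparison. The best cut-off maximizes sensitivity + specificity with ties
resolved to the lower threshold. Calibration uses ten half-open bins
[0, 0.1), …, [0.9, 1.0] — the half-open reading resolves the ambiguity of
"0–10%" vs "10.1–20%" bin descriptions. Per-stratum AUC reports strata
missing a class as undefined rather than dropping them. A constant
predictor scores AUC 0.50 exactly under the rank formulation, which the
suite asserts against an exhaustive pair-counting oracle.

## The synthetic cohort

The generator emulates the *structure* of a longitudinal oncology EMR
corpus: multiple note types, irregular visit gaps (log-normal, median 12
days), ~80% survival-positive visit labels, censored survivors, same-day
visits, and a plantable textual signal: notes of dying patients dated
within 90 days of death contain, with probability `signal_strength`, a
fatal-signal phrase built from controlled-term surface forms (hospice,
palliative, deteriorating, …) that the dictionary maps. Label prevalence is
met *by construction*: visit timelines are generated first, then patients
are converted to deceased (in seeded random order, death 1–45 days after
the last visit) until the negative-label share reaches the target —
analytic calibration of a death probability is inaccurate under skewed
visit-count laws, where short-history patients contribute all-negative
label runs.

**Visits-per-patient law.** The default is memoryless: 2 + geometric with
mean 8. This is a deliberate departure from the heavy-tailed law real
cohorts show, and the reason is statistical, not cosmetic. Negative labels
can only sit within ~91 days of a death, i.e. at the *end* of a dying
patient's record. If record length has a non-constant discrete hazard, the
timestep index alone predicts the label, and a recurrent model will exploit
it: under a log-normal law the position-only Bayes AUC is about 0.68 with
no textual signal at all. With a memoryless law the "record ends soon"
hazard is flat in position, and the no-signal experiment sits at chance —
which is precisely what makes the planted-signal experiment interpretable:
whatever the model recovers must have come through the text. The
heavy-tailed law remains available (`visits_law = "lognormal"`) for realism
and for exercising truncation, and the cap (default 1200) keeps extreme
records finite. Residual leakage survives at the truncation boundary (all
records longer than `max_len` end at the same frame position), so the
no-signal AUC at modest test sizes (~75 held-out patients) varies by a few
points around 0.5 across seeds.

What the generator does **not** emulate: real clinical language (templated
sentences over a small vocabulary), section structure, misspellings,
note-length variation, terminal-phase visit densification, or real
controlled-term inventories (the bundled dictionary is a ~60-entry
synthetic miniature modelled on CLEVER's classes). Passing tests therefore
demonstrate that the pipeline's machinery is correct and that it recovers a
textual signal when one exists — not that these hyperparameters reach any
particular accuracy on real notes.

## Problem sizes and defaults used in validation

The validation experiments use 500 patients, 32-dimensional embeddings,
skip-gram window 5 with 3 passes, sequence length 20 and 30 training
epochs — sizes at which the full double experiment (signal and null) runs
in about a minute. The reference settings from the method's original
deployment (700 dimensions, window 30, sequence length 1000, ~100 epochs,
ten-thousand-patient cohorts) remain the documented defaults of the
underlying functions; nothing in the implementation depends on the smaller
sizes.

## Known limitations

- The stem index drops ambiguous stem keys (two surfaces, one stem,
  different controlled terms) with a warning; a frequency-based resolution
  would be better with a real dictionary.
- Skip-gram determinism holds in the single-threaded trainer; there is no
  multi-worker mode.
- Batch-normalization statistics are shared across timesteps; per-timestep
  statistics were considered and rejected (see above), but neither reading
  is certain.
- The explanation report locates matched surface forms in raw text by
  re-normalizing raw words and allowing stopword gaps; heavily rephrased
  spans (e.g. matches that exist only after collocation merging) can fail
  to locate and are silently omitted from the findings list.
- The no-signal chance band is exact only as test-set size grows; at the
  validation sizes it is seed-sensitive within a few points of 0.5.
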