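#' Run the full pipeline on a synthetic cohort
#'
#' Convenience wrapper chaining every stage: cohort simulation, condensing,
#' collocation fitting and merging, dictionary mapping, embedding training,
#' note vectorization, sequence building, patient-level splitting, model
#' training, prediction on the held-out test split and evaluation. Fully
#' deterministic given `seed`.
#'
#' @param cohort a [cohort_config()] (its seed is used for simulation).
#' @param dict_path controlled-term dictionary TSV; default the bundled
#'   miniature dictionary.
#' @param dim,window,min_count,embed_epochs skip-gram parameters for the
#'   embedding stage (defaults sized for synthetic corpora).
#' @param cwindow context half-width for note vectors.
#' @param colloc_min_count,colloc_top_k collocation parameters (defaults
#'   sized for synthetic corpora; the method's reference defaults are
#'   50 / 1000).
#' @param max_len sequence length after padding/truncation.
#' @param fractions train/validation/test patient fractions.
#' @param model a [model_config()] or NULL for defaults at the embedding
#'   dimension.
#' @param n_boot bootstrap replicates in evaluation.
#' @param seed master seed for embedding, splitting, training, bootstrap.
#' @param verbose print progress.
#' @return list: `cohort`, `mapped`, `embedding`, `vectors`, `dataset`,
#'   `splits`, `model`, `predictions`, `report`.
#' @export
run_pipeline <- function(cohort = cohort_config(),
                         dict_path = example_dictionary_path(),
                         dim = 32L, window = 5L, min_count = 5L,
                         embed_epochs = 3L, cwindow = 15L,
                         colloc_min_count = 25L, colloc_top_k = 50L,
                         max_len = 20L, fractions = c(0.7, 0.15, 0.15),
                         model = NULL, n_boot = 100L, seed = 1L,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("simulating cohort")
  coh <- generate_cohort(cohort)
  say("condensing ", nrow(coh$notes), " notes")
  condensed <- condense_notes(coh$notes)
  colloc <- fit_collocations(condensed, min_count = colloc_min_count,
                             top_k = colloc_top_k)
  merged <- apply_collocations_corpus(condensed, colloc)
  dict <- load_dictionary(dict_path)
  mapped <- map_corpus(merged, dict)
  say("training embeddings")
  emb <- train_embeddings(mapped, dim = dim, window = window,
                          min_count = min_count, epochs = embed_epochs,
                          seed = seed)
  vectors <- vectorize_corpus(mapped, emb, cwindow = cwindow)
  ds <- build_sequences(vectors, coh$notes, coh$outcomes, max_len = max_len)
  splits <- split_cohort(ds, fractions, seed = seed)
  if (is.null(model)) model <- model_config(D = dim, seed = seed)
  say("training model (", model$epochs, " epochs)")
  fit <- train_model(splits$train, splits$validation, model, verbose = verbose)
  pred <- predict_sequences(fit, splits$test)
  report <- evaluate_predictions(pred, n_boot = n_boot, seed = seed)
  list(cohort = coh, collocations = colloc, dictionary = dict,
       mapped = mapped, embedding = emb, vectors = vectors, dataset = ds,
       splits = splits, model = fit, predictions = pred, report = report)
}
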