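# Shared fixtures built in code at test time.

# write a tiny dictionary TSV and return its path
tiny_dict_file <- function(entries) {
  path <- tempfile(fileext = ".tsv")
  writeLines(vapply(names(entries), function(s)
    paste(s, entries[[s]], sep = "\t"), character(1)), path)
  path
}

# a minimal mapped_note built by hand (tokens + controlled-term positions)
hand_mapped_note <- function(tokens, positions) {
  structure(list(tokens = tokens,
                 mapped = data.frame(pos = positions,
                                     span = rep(1L, length(positions)),
                                     cterm = tokens[positions],
                                     matched = tokens[positions],
                                     stringsAsFactors = FALSE)),
            class = "mapped_note")
}

# a hand-built embedding model from a named list of numeric vectors
hand_embedding <- function(vectors) {
  m <- do.call(rbind, vectors)
  rownames(m) <- names(vectors)
  structure(list(vectors = m, counts = rep(10L, nrow(m)), dim = ncol(m),
                 window = 5L, min_count = 1L, epochs = 1L, seed = 1L),
            class = "embedding_model")
}

# independent oracle: two-level nested mean over controlled-term windows,
# written as plain loops so it shares no code with note_vector()
oracle_note_vector <- function(tokens, positions, vecs, cwindow) {
  D <- length(vecs[[1]])
  acc <- numeric(D); used <- 0
  for (p in positions) {
    lo <- max(1, p - cwindow); hi <- min(length(tokens), p + cwindow)
    ctx <- numeric(D); k <- 0
    for (j in lo:hi) {
      w <- tokens[j]
      if (!is.null(vecs[[w]])) {
        ctx <- ctx + vecs[[w]]; k <- k + 1
      }
    }
    if (k > 0) {
      acc <- acc + ctx / k
      used <- used + 1
    }
  }
  if (used == 0) numeric(D) else acc / used
}

# independent oracle: AUC by exhaustive pair counting, ties count 1/2
oracle_pair_auc <- function(scores, pos) {
  wins <- 0; total <- 0
  for (i in which(pos)) {
    for (j in which(!pos)) {
      total <- total + 1
      if (scores[i] > scores[j]) wins <- wins + 1
      else if (scores[i] == scores[j]) wins <- wins + 0.5
    }
  }
  wins / total
}

# a small trained pipeline shared across model tests (memoized)
.small_fit_cache <- new.env(parent = emptyenv())
small_trained_pipeline <- function() {
  if (is.null(.small_fit_cache$fit)) {
    .small_fit_cache$fit <- run_pipeline(
      cohort = cohort_config(n_patients = 120, signal_strength = 1, seed = 5),
      dim = 12, window = 4, embed_epochs = 2, max_len = 12,
      model = model_config(D = 12, epochs = 8, seed = 5),
      n_boot = 0, seed = 5)
  }
  .small_fit_cache$fit
}
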