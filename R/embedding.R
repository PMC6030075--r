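#' Train skip-gram word embeddings on a mapped corpus
#'
#' Skip-gram with negative sampling trained over the corpus token streams.
#' Tokens occurring fewer than `min_count` times get no vector and are
#' dropped from the training streams. Training is single-threaded with an
#' internal seeded RNG, so the same seed, corpus and parameters always give
#' identical vectors.
#'
#' @param corpus a `mapped_corpus` (or any list of token vectors /
#'   `mapped_note` objects).
#' @param dim embedding dimension; default 700.
#' @param window training context half-width; a per-position effective width
#'   is drawn uniformly in 1..window, as in standard word2vec. Default 30.
#' @param min_count minimum corpus count for a token to get a vector;
#'   default 5.
#' @param epochs passes over the corpus; default 5.
#' @param negative negative samples per positive pair; default 5.
#' @param alpha initial learning rate, decayed linearly; default 0.025.
#' @param seed integer RNG seed.
#' @return an object of class `embedding_model`: list with `vectors`
#'   (vocab x dim matrix, rownames = tokens), `counts`, and the training
#'   parameters.
#' @export
train_embeddings <- function(corpus, dim = 700L, window = 30L, min_count = 5L,
                             epochs = 5L, negative = 5L, alpha = 0.025,
                             seed = 1L) {
  stopifnot(dim >= 1L, window >= 1L, min_count >= 1L, epochs >= 1L)
  streams <- lapply(corpus, function(x) if (inherits(x, "mapped_note")) x$tokens else x)
  toks <- unlist(streams, use.names = FALSE)
  if (length(toks) == 0L) stop("empty corpus: nothing to train on")
  cnt <- table(toks)
  cnt <- cnt[cnt >= min_count]
  if (length(cnt) == 0L)
    stop("no token reaches min_count = ", min_count, "; corpus too small")
  # stable vocabulary order: frequency desc, then lexicographic
  cnt <- cnt[order(-as.integer(cnt), names(cnt))]
  vocab <- names(cnt)

  sent <- lapply(streams, function(s) {
    ix <- match(s, vocab)
    ix <- ix[!is.na(ix)] - 1L  # 0-based; out-of-vocabulary tokens dropped
    as.integer(ix)
  })
  sent <- sent[lengths(sent) > 0L]
  vec <- sg_train_cpp(sent, length(vocab), as.numeric(cnt), as.integer(dim),
                      as.integer(window), as.integer(negative),
                      as.integer(epochs), alpha, alpha * 1e-4, 0.75,
                      as.integer(seed))
  rownames(vec) <- vocab
  structure(list(vectors = vec, counts = as.integer(cnt), dim = as.integer(dim),
                 window = as.integer(window), min_count = as.integer(min_count),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat("embedding_model:", nrow(x$vectors), "tokens x", x$dim,
      "dims (window", x$window, ", min_count", x$min_count, ")\n")
  invisible(x)
}

#' Context-aware note vector
#'
#' For every controlled-term occurrence in a mapped note, the context vector
#' is the arithmetic mean of the embedding vectors of the tokens in the
#' occurrence's window — the term itself plus up to `cwindow` tokens on each
#' side, truncated at the note boundaries. Tokens without a vector are
#' skipped and do not enter the denominator. The note vector is the mean of
#' the per-occurrence context vectors:
#' v_note = (1/N) * sum_c (1/n_c) * sum_w v_w.
#' A note with no controlled-term occurrence (or whose windows contain no
#' in-vocabulary token) gets the all-zeros vector.
#'
#' @param note a `mapped_note`.
#' @param model an `embedding_model`.
#' @param cwindow tokens on each side of the occurrence; default 15.
#' @return an object of class `note_vector`: list with `vector` (length
#'   `model$dim`), `n_cterms`, and `contexts` (list of window index spans).
#' @export
note_vector <- function(note, model, cwindow = 15L) {
  stopifnot(inherits(note, "mapped_note"), inherits(model, "embedding_model"),
            cwindow >= 0L)
  toks <- note$tokens
  n <- length(toks)
  occ <- note$mapped$pos
  D <- model$dim
  v <- numeric(D)
  contexts <- list()
  used <- 0L
  if (length(occ) > 0L && n > 0L) {
    rows <- match(toks, rownames(model$vectors))
    for (p in occ) {
      lo <- max(1L, p - cwindow); hi <- min(n, p + cwindow)
      ridx <- rows[lo:hi]
      ridx <- ridx[!is.na(ridx)]
      contexts[[length(contexts) + 1L]] <- c(lo, hi)
      if (length(ridx) == 0L) next
      ctx <- colMeans(model$vectors[ridx, , drop = FALSE])
      v <- v + ctx
      used <- used + 1L
    }
  }
  if (used > 0L) v <- v / used
  structure(list(vector = v, n_cterms = used, contexts = contexts),
            class = "note_vector")
}

#' Vectorize a mapped corpus
#'
#' One context-aware vector per note; the result does not depend on the
#' input order of the notes.
#'
#' @param corpus a `mapped_corpus`.
#' @param model an `embedding_model`.
#' @param cwindow tokens on each side of a controlled-term occurrence.
#' @return numeric matrix, one row per note, rownames = note ids.
#' @export
vectorize_corpus <- function(corpus, model, cwindow = 15L) {
  if (missing(model) || !inherits(model, "embedding_model"))
    stop("an embedding_model is required")
  out <- matrix(0, nrow = length(corpus), ncol = model$dim)
  rownames(out) <- names(corpus)
  for (i in seq_along(corpus))
    out[i, ] <- note_vector(corpus[[i]], model, cwindow)$vector
  out
}

#' Persist / load an embedding model in word2vec text format
#'
#' Header line "vocab_size dim", then one line per token: the token followed
#' by its vector entries, space-separated.
#'
#' @param model an `embedding_model`.
#' @param path file path.
#' @export
write_embedding <- function(model, path) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(model$vectors), model$dim), con, useBytes = TRUE)
  lines <- vapply(seq_len(nrow(model$vectors)), function(i) {
    paste(rownames(model$vectors)[i],
          paste(sprintf("%.17g", model$vectors[i, ]), collapse = " "))
  }, character(1))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  n <- hdr[1]; d <- hdr[2]
  vec <- matrix(0, nrow = n, ncol = d)
  toks <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], " ", fixed = TRUE)[[1]]
    toks[i] <- f[1]
    vec[i, ] <- as.numeric(f[-1])
  }
  rownames(vec) <- toks
  structure(list(vectors = vec, counts = NA_integer_, dim = d,
                 window = NA_integer_, min_count = NA_integer_,
                 epochs = NA_integer_, seed = NA_integer_),
            class = "embedding_model")
}
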