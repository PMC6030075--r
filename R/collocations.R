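#' Fit PMI bigram collocations
#'
#' Counts adjacent token pairs over a condensed corpus and scores them by
#' pointwise mutual information, PMI(a,b) = log( c(a,b) * T / (c(a) * c(b)) ),
#' where c(a), c(b) are token occurrence counts and T is the total number of
#' adjacent pairs in the corpus. Pairs occurring fewer than `min_count` times
#' are discarded; the `top_k` survivors by PMI are selected for merging.
#' Ties are broken by higher pair count, then lexicographically, so the
#' selection is deterministic. Pairs are never formed across note
#' boundaries, and tokens that already contain an underscore (relative-date
#' tokens, previously merged bigrams) are not collocation candidates.
#'
#' @param corpus a `condensed_corpus` (named list of token vectors).
#' @param min_count minimum corpus count of a bigram; default 50.
#' @param top_k number of bigrams selected; default 1000.
#' @return an object of class `collocation_model`: a data frame with columns
#'   `token_a`, `token_b`, `count`, `pmi`, `selected`, plus attributes
#'   `min_count`, `top_k`.
#' @export
fit_collocations <- function(corpus, min_count = 50L, top_k = 1000L) {
  stopifnot(min_count >= 1L, top_k >= 0L)
  if (length(corpus) == 0L || sum(lengths(corpus)) == 0L)
    stop("empty corpus: no tokens to fit collocations on")

  toks <- unlist(corpus, use.names = FALSE)
  uni <- table(toks)

  a <- unlist(lapply(corpus, function(t) if (length(t) >= 2L) t[-length(t)] else character(0)),
              use.names = FALSE)
  b <- unlist(lapply(corpus, function(t) if (length(t) >= 2L) t[-1L] else character(0)),
              use.names = FALSE)
  if (length(a) == 0L) {
    model <- data.frame(token_a = character(0), token_b = character(0),
                        count = integer(0), pmi = numeric(0),
                        selected = logical(0), stringsAsFactors = FALSE)
    return(structure(model, class = c("collocation_model", "data.frame"),
                     min_count = min_count, top_k = top_k))
  }
  total_pairs <- length(a)

  key <- paste(a, b, sep = "\r")
  cnt <- table(key)
  pk <- strsplit(names(cnt), "\r", fixed = TRUE)
  ta <- vapply(pk, `[`, character(1), 1L)
  tb <- vapply(pk, `[`, character(1), 2L)
  count <- as.integer(cnt)

  pmi <- log(count * total_pairs / (as.numeric(uni[ta]) * as.numeric(uni[tb])))

  keep <- count >= min_count & !grepl("_", ta, fixed = TRUE) &
    !grepl("_", tb, fixed = TRUE)
  model <- data.frame(token_a = ta, token_b = tb, count = count, pmi = pmi,
                      selected = FALSE, stringsAsFactors = FALSE)
  cand <- which(keep)
  if (length(cand) > 0L && top_k > 0L) {
    ord <- cand[order(-model$pmi[cand], -model$count[cand],
                      model$token_a[cand], model$token_b[cand])]
    model$selected[utils::head(ord, top_k)] <- TRUE
  }
  model <- model[order(-model$selected, -model$pmi, -model$count,
                       model$token_a, model$token_b), , drop = FALSE]
  rownames(model) <- NULL
  structure(model, class = c("collocation_model", "data.frame"),
            min_count = min_count, top_k = top_k)
}

#' Merge selected collocations into single tokens
#'
#' Greedy left-to-right, non-overlapping: at each position, if the token and
#' its right neighbour form a selected bigram they are joined with an
#' underscore and the scan continues after the pair.
#'
#' @param tokens a condensed token vector.
#' @param model a `collocation_model` from [fit_collocations()].
#' @return token vector with selected bigrams merged.
#' @export
apply_collocations <- function(tokens, model) {
  sel <- model[model$selected, , drop = FALSE]
  if (nrow(sel) == 0L || length(tokens) < 2L) return(tokens)
  selected <- paste(sel$token_a, sel$token_b, sep = "_")
  n <- length(tokens)
  joined <- paste(tokens[-n], tokens[-1L], sep = "_")
  hit <- joined %in% selected
  if (!any(hit)) return(tokens)
  out <- character(n)
  k <- 0L; i <- 1L
  while (i <= n) {
    if (i < n && hit[i]) {
      k <- k + 1L; out[k] <- joined[i]; i <- i + 2L
    } else {
      k <- k + 1L; out[k] <- tokens[i]; i <- i + 1L
    }
  }
  out[seq_len(k)]
}

#' Apply collocation merging to a whole corpus
#' @param corpus a `condensed_corpus`.
#' @param model a `collocation_model`.
#' @return a `condensed_corpus` with merged tokens.
#' @export
apply_collocations_corpus <- function(corpus, model) {
  out <- lapply(corpus, apply_collocations, model = model)
  structure(out, class = "condensed_corpus")
}

#' Persist / load a collocation model as tab-separated text
#'
#' Columns: token_a, token_b, count, pmi, selected_flag.
#' @param model a `collocation_model`.
#' @param path file path.
#' @export
write_collocations <- function(model, path) {
  df <- as.data.frame(model)
  df$selected <- as.integer(df$selected)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_collocations
#' @return `read_collocations()` returns the `collocation_model`.
#' @export
read_collocations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  df$selected <- as.logical(df$selected)
  structure(df, class = c("collocation_model", "data.frame"))
}
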