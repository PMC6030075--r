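#' Load a controlled-term dictionary
#'
#' Reads a two-column tab-separated file (UTF-8, no header): surface term,
#' controlled term. Controlled terms are uppercased canonical tokens (e.g.
#' NEGEX, FAMILY, RISK, QUAL) that surface words and phrases are normalized
#' to. Two lookup indexes are built: an exact index keyed by the tokenized
#' lowercase surface form, and a stem index keyed by the surface form passed
#' through the same condenser rules (stopword removal + Porter stemming) as
#' the note text, so that pipeline stages agree on roots.
#'
#' Duplicate identical entries are collapsed; a surface form mapping to two
#' different controlled terms is a load error. Stem-index keys that become
#' ambiguous (two surfaces, same stem key, different controlled terms) are
#' dropped from the stem index with a warning. A surface form equal to the
#' lowercase of a controlled term is rejected so that mapping stays
#' idempotent.
#'
#' @param path path to the TSV file.
#' @param max_span longest surface phrase, in condensed tokens, indexed for
#'   matching (default 6).
#' @return an object of class `term_dictionary`.
#' @export
load_dictionary <- function(path, max_span = 6L) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(structure(list(entries = data.frame(surface = character(0),
                                               cterm = character(0)),
                          exact = list(), stem = list(),
                          controlled_terms = character(0),
                          max_span = max_span),
                     class = "term_dictionary"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L)
    stop("malformed dictionary line(s) (expected 2 tab-separated fields): ",
         paste(bad, collapse = ", "))
  surface <- trimws(vapply(parts, `[`, character(1), 1L))
  cterm <- toupper(trimws(vapply(parts, `[`, character(1), 2L)))

  df <- unique(data.frame(surface = tolower(surface), cterm = cterm,
                          stringsAsFactors = FALSE))
  dup <- df$surface[duplicated(df$surface)]
  if (length(dup) > 0L)
    stop("conflicting dictionary entries: surface form(s) mapped to multiple ",
         "controlled terms: ", paste(unique(dup), collapse = ", "))
  exact <- list(); stem <- list(); stem_conflict <- character(0)
  for (i in seq_len(nrow(df))) {
    toks <- tokenize(df$surface[i])
    if (length(toks) == 0L) next
    ek <- paste(toks, collapse = " ")
    exact[[ek]] <- df$cterm[i]
    ctoks <- porter_stem(toks[!(toks %in% default_stoplist())])
    if (length(ctoks) >= 1L && length(ctoks) <= max_span) {
      sk <- paste(ctoks, collapse = " ")
      if (!is.null(stem[[sk]]) && stem[[sk]] != df$cterm[i]) {
        stem_conflict <- c(stem_conflict, sk)
      } else {
        stem[[sk]] <- df$cterm[i]
      }
    }
  }
  if (length(stem_conflict) > 0L) {
    warning("ambiguous stem key(s) dropped from stem index: ",
            paste(unique(stem_conflict), collapse = ", "))
    stem[unique(stem_conflict)] <- NULL
  }
  # idempotence guard: a controlled term must never itself be matchable
  bad <- unique(df$cterm[df$cterm %in% c(names(exact), names(stem))])
  if (length(bad) > 0L)
    stop("controlled term(s) collide with surface forms (mapping would not ",
         "be idempotent): ", paste(bad, collapse = ", "))
  structure(list(entries = df, exact = exact, stem = stem,
                 controlled_terms = sort(unique(df$cterm)),
                 max_span = max_span),
            class = "term_dictionary")
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat("term_dictionary:", nrow(x$entries), "entries,",
      length(x$controlled_terms), "controlled terms\n")
  invisible(x)
}

#' Map condensed tokens to controlled terms
#'
#' Scans the condensed token stream left to right; at each position the
#' longest matching dictionary span (up to the dictionary's `max_span`
#' condensed tokens) wins, trying the exact surface index before the stem
#' index at every span length. Matched spans are replaced by the controlled
#' term; unmatched tokens pass through. Positions of matches are recorded
#' for downstream explanation.
#'
#' @param tokens a condensed (and collocation-merged) token vector.
#' @param dict a `term_dictionary`.
#' @return an object of class `mapped_note`: list with `tokens` (the mapped
#'   stream) and `mapped` (data frame: `pos` = index in the mapped stream,
#'   `span` = number of input tokens consumed, `cterm`, `matched` = the
#'   matched input tokens pasted with spaces).
#' @export
map_terms <- function(tokens, dict) {
  stopifnot(inherits(dict, "term_dictionary"))
  n <- length(tokens)
  if (n == 0L) {
    return(structure(list(tokens = character(0),
                          mapped = data.frame(pos = integer(0), span = integer(0),
                                              cterm = character(0),
                                              matched = character(0),
                                              stringsAsFactors = FALSE)),
                     class = "mapped_note"))
  }
  e_keys <- names(dict$exact); s_keys <- names(dict$stem)
  if (is.null(e_keys)) e_keys <- character(0)
  if (is.null(s_keys)) s_keys <- character(0)
  e_single <- e_keys[!grepl(" ", e_keys, fixed = TRUE)]
  s_single <- s_keys[!grepl(" ", s_keys, fixed = TRUE)]
  e_multi <- e_keys[grepl(" ", e_keys, fixed = TRUE)]
  s_multi <- s_keys[grepl(" ", s_keys, fixed = TRUE)]
  first_of <- function(k) vapply(strsplit(k, " ", fixed = TRUE), `[`, character(1), 1L)
  phrase_first <- unique(c(first_of(e_multi), first_of(s_multi)))

  # vectorized single-token lookups (exact surface beats stem)
  m_e <- match(tokens, e_single)
  m_s <- match(tokens, s_single)
  starts_phrase <- tokens %in% phrase_first

  out <- character(n)
  pos <- integer(n); span <- integer(n); cterm <- character(n)
  matched <- character(n)
  k <- 0L; nm <- 0L; i <- 1L
  max_span <- min(dict$max_span, n)
  while (i <= n) {
    hit <- NULL; hit_s <- 1L
    if (starts_phrase[i] && i < n && max_span >= 2L) {
      for (s in seq(min(max_span, n - i + 1L), 2L)) {
        key <- paste(tokens[i:(i + s - 1L)], collapse = " ")
        ct <- dict$exact[[key]]
        if (is.null(ct)) ct <- dict$stem[[key]]
        if (!is.null(ct)) { hit <- ct; hit_s <- s; break }
      }
    }
    if (is.null(hit)) {
      if (!is.na(m_e[i])) hit <- dict$exact[[e_single[m_e[i]]]]
      else if (!is.na(m_s[i])) hit <- dict$stem[[s_single[m_s[i]]]]
    }
    k <- k + 1L
    if (!is.null(hit)) {
      out[k] <- hit
      nm <- nm + 1L
      pos[nm] <- k; span[nm] <- hit_s; cterm[nm] <- hit
      matched[nm] <- paste(tokens[i:(i + hit_s - 1L)], collapse = " ")
      i <- i + hit_s
    } else {
      out[k] <- tokens[i]
      i <- i + 1L
    }
  }
  idx <- seq_len(nm)
  structure(list(tokens = out[seq_len(k)],
                 mapped = data.frame(pos = pos[idx], span = span[idx],
                                     cterm = cterm[idx], matched = matched[idx],
                                     stringsAsFactors = FALSE)),
            class = "mapped_note")
}

#' Map a whole condensed corpus
#' @param corpus a `condensed_corpus`.
#' @param dict a `term_dictionary`.
#' @return a named list of `mapped_note` objects (class `mapped_corpus`).
#' @export
map_corpus <- function(corpus, dict) {
  out <- lapply(corpus, map_terms, dict = dict)
  structure(out, class = "mapped_corpus")
}

#' Vocabulary reduction achieved by dictionary mapping
#'
#' The fraction of distinct tokens removed: 1 - |vocab after| / |vocab before|.
#'
#' @param before,after corpora (lists of token vectors, or `mapped_corpus`;
#'   `mapped_note` elements contribute their `tokens`).
#' @return a fraction in \[0, 1).
#' @export
vocabulary_reduction <- function(before, after) {
  vb <- corpus_vocab(before); va <- corpus_vocab(after)
  if (length(vb) == 0L || length(va) == 0L)
    stop("empty corpus: vocabulary reduction undefined")
  1 - length(va) / length(vb)
}

corpus_vocab <- function(corpus) {
  toks <- unlist(lapply(corpus, function(x) {
    if (inherits(x, "mapped_note")) x$tokens else x
  }), use.names = FALSE)
  unique(toks)
}

#' Path to the bundled miniature controlled-term dictionary
#'
#' A small synthetic dictionary in the CLEVER two-column TSV format,
#' modelled on its term classes (NEGEX, FAMILY, RISK, QUAL) plus toy
#' oncology terms. It is a testing fixture, not a real lexicon.
#'
#' @return file path of the TSV inside the installed package.
#' @export
example_dictionary_path <- function() {
  system.file("extdata", "dictionary_synthetic_mini.tsv", package = "notecast",
              mustWork = TRUE)
}
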