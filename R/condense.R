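#' @title Report condensing: tokenization and text normalization
#' @description Cleaning stage for raw clinical note text: relative-date
#'   conversion, lowercasing, tokenization, number-to-word conversion,
#'   stopword removal and Porter stemming. Collocation merging is a separate
#'   step (see [fit_collocations()]).
#' @name condense
NULL

# Closed-class function words only (articles, determiners, pronouns,
# prepositions, conjunctions). Negations are deliberately absent: "no",
# "not", "nor", "never", "without" must survive condensing because the
# controlled-term dictionary maps them (NEGEX).
.stoplist <- c(
  "a", "an", "the", "this", "that", "these", "those",
  "i", "me", "my", "mine", "we", "us", "our", "ours",
  "you", "your", "yours", "he", "him", "his", "she", "her", "hers",
  "it", "its", "they", "them", "their", "theirs",
  "of", "in", "on", "at", "by", "for", "with", "from", "to", "into",
  "onto", "over", "under", "between", "among", "through", "during",
  "about", "against", "above", "below", "up", "down", "out", "off",
  "and", "or", "but", "so", "if", "than", "then", "as", "because",
  "while", "although", "though", "when", "where", "which", "who",
  "whom", "whose", "what", "there", "here", "again", "further",
  "each", "few", "more", "most", "other", "some", "such", "only",
  "own", "same", "both", "all", "any", "very", "per", "via"
)

#' Default English stoplist
#'
#' Closed-class function words with clinical negations ("no", "not", ...)
#' deliberately excluded, since negations carry meaning through the
#' controlled-term dictionary (NEGEX class).
#'
#' @return character vector of stopwords.
#' @export
default_stoplist <- function() .stoplist

.num_words <- c(
  "zero", "one", "two", "three", "four", "five", "six", "seven", "eight",
  "nine", "ten", "eleven", "twelve", "thirteen", "fourteen", "fifteen",
  "sixteen", "seventeen", "eighteen", "nineteen", "twenty"
)

# integer >= 0 to a token: 0-20 as words, larger as magnitude tokens so the
# vocabulary stays bounded
int_to_token <- function(n) {
  ifelse(n <= 20L, .num_words[n + 1L],
    ifelse(n < 100L, "num_tens",
      ifelse(n < 1000L, "num_hundreds",
        ifelse(n < 1e6, "num_thousands", "num_large"))))
}

# count word for relative-date buckets; counts beyond twenty collapse
count_word <- function(n) ifelse(n <= 20L, .num_words[pmin(n, 20L) + 1L], "many")

round_half_up <- function(x) floor(x + 0.5)

#' Bucket a day gap into a relative-date token
#'
#' Granularity grows with the gap: days (1-6), weeks (1-4, up to 30 days),
#' months (1-11, month = 30.44 days) and years (year = 365.25 days), rounded
#' half up. A zero gap is "same_day"; negative gaps (mentioned date after the
#' visit) use the "_ahead" suffix.
#'
#' @param gap_days integer vector of day gaps (visit date minus mentioned date).
#' @return character vector of bucket tokens, e.g. "three_month_ago".
#' @export
gap_token <- function(gap_days) {
  vapply(as.integer(gap_days), function(d) {
    if (is.na(d)) return(NA_character_)
    suffix <- if (d < 0) "ahead" else "ago"
    d <- abs(d)
    if (d == 0L) return("same_day")
    if (d < 7L) return(paste(count_word(d), "day", suffix, sep = "_"))
    if (d <= 30L) {
      w <- max(1L, min(4L, as.integer(round_half_up(d / 7))))
      return(paste(count_word(w), "week", suffix, sep = "_"))
    }
    m <- as.integer(round_half_up(d / 30.44))
    if (m < 12L) return(paste(count_word(max(1L, m)), "month", suffix, sep = "_"))
    y <- max(1L, as.integer(round_half_up(d / 365.25)))
    paste(count_word(y), "year", suffix, sep = "_")
  }, character(1))
}

.month_names <- c("january", "february", "march", "april", "may", "june",
                  "july", "august", "september", "october", "november",
                  "december")

#' Replace dates mentioned in text by relative-gap tokens
#'
#' Detects ISO-8601 (YYYY-MM-DD), MM/DD/YYYY and "Month D, YYYY" dates,
#' computes the gap to the visit date and substitutes the [gap_token()]
#' bucket. Strings that look like dates but do not parse (e.g. month 13) are
#' left untouched.
#'
#' @param text character vector of raw note text.
#' @param visit_date the visit `Date` (scalar, recycled over `text`).
#' @return character vector with dates replaced.
#' @export
normalize_dates <- function(text, visit_date) {
  visit_date <- as.Date(visit_date)
  stopifnot(!is.na(visit_date))
  pats <- c(
    iso = "\\b\\d{4}-\\d{2}-\\d{2}\\b",
    us  = "\\b\\d{1,2}/\\d{1,2}/\\d{4}\\b",
    txt = paste0("\\b(", paste(c(.month_names, paste0(toupper(substr(.month_names, 1, 1)),
            substr(.month_names, 2, 99))), collapse = "|"),
            ")\\s+\\d{1,2},\\s*\\d{4}\\b")
  )
  parse_one <- function(s, kind) {
    switch(kind,
      iso = as.Date(s, format = "%Y-%m-%d"),
      us  = as.Date(s, format = "%m/%d/%Y"),
      txt = as.Date(tolower(s), format = "%B %d, %Y"))
  }
  vapply(text, function(tx) {
    for (kind in names(pats)) {
      m <- gregexpr(pats[[kind]], tx, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      ss <- regmatches(tx, list(m))[[1]]
      repl <- vapply(ss, function(s) {
        d <- parse_one(s, kind)
        if (is.na(d)) s else gap_token(as.integer(visit_date - d))
      }, character(1), USE.NAMES = FALSE)
      regmatches(tx, list(m)) <- list(repl)
    }
    tx
  }, character(1), USE.NAMES = FALSE)
}

#' Tokenize text
#'
#' Lowercases and splits on any character that is not a letter, digit,
#' hyphen or underscore; leading/trailing hyphens are stripped. Underscores
#' are token-internal so that relative-date tokens ("three_month_ago") and
#' merged collocations survive.
#'
#' @param text character scalar.
#' @return character vector of tokens (possibly empty).
#' @export
tokenize <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9_-]+")[[1]]
  toks <- gsub("^-+|-+$", "", toks)
  toks[nzchar(toks)]
}

#' Condense one raw note
#'
#' Applies, in order: relative-date conversion, tokenization, number-to-word
#' conversion, stopword removal, Porter stemming. Tokens containing digits,
#' hyphens or underscores (dates, magnitudes, merged bigrams) pass through
#' the stemmer unchanged.
#'
#' @param text raw note text (may be empty).
#' @param visit_date the visit `Date`.
#' @param stoplist character vector of stopwords; default [default_stoplist()].
#' @return character vector of condensed tokens.
#' @export
condense <- function(text, visit_date, stoplist = default_stoplist()) {
  toks <- tokenize(normalize_dates(text, visit_date))
  if (length(toks) == 0L) return(character(0))
  is_int <- grepl("^[0-9]+$", toks)
  if (any(is_int)) toks[is_int] <- int_to_token(as.integer(toks[is_int]))
  toks <- toks[!(toks %in% stoplist)]
  porter_stem(toks)
}

#' Condense a corpus of notes
#'
#' @param notes a notes data frame (see [read_notes()]): columns
#'   `patient_id`, `note_id`, `visit_date`, `note_type`, `text`.
#' @param stoplist stopword vector.
#' @return a named list of condensed token vectors keyed by `note_id`,
#'   with class `"condensed_corpus"`.
#' @export
condense_notes <- function(notes, stoplist = default_stoplist()) {
  stopifnot(is.data.frame(notes), nrow(notes) > 0L)
  texts <- notes$text
  # relative-date conversion only where a date-like pattern can occur
  has_date <- grepl("\\d{4}-\\d{2}-\\d{2}|\\d{1,2}/\\d{1,2}/\\d{4}", texts) |
    grepl(paste(.month_names, collapse = "|"), texts, ignore.case = TRUE)
  if (any(has_date)) {
    idx <- which(has_date)
    texts[idx] <- vapply(idx, function(i)
      normalize_dates(texts[i], notes$visit_date[i]), character(1))
  }
  tok_lists <- strsplit(tolower(texts), "[^a-z0-9_-]+")
  flat <- unlist(tok_lists, use.names = FALSE)
  note_of <- rep.int(seq_along(tok_lists), lengths(tok_lists))
  flat <- gsub("^-+|-+$", "", flat)
  keep <- nzchar(flat)
  flat <- flat[keep]; note_of <- note_of[keep]
  is_int <- grepl("^[0-9]+$", flat)
  if (any(is_int)) flat[is_int] <- int_to_token(as.integer(flat[is_int]))
  keep <- !(flat %in% stoplist)
  flat <- porter_stem(flat[keep]); note_of <- note_of[keep]
  out <- split(flat, factor(note_of, levels = seq_along(tok_lists)))
  names(out) <- notes$note_id
  out <- lapply(out, as.character)
  structure(out, class = "condensed_corpus")
}
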