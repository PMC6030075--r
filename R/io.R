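#' Read and write visit notes as JSON-lines
#'
#' One JSON object per line with fields `patient_id`, `note_id`,
#' `visit_date` (ISO-8601), `note_type`, `text`.
#'
#' @param notes a data frame with those columns.
#' @param path file path.
#' @export
write_notes <- function(notes, path) {
  stopifnot(all(c("patient_id", "note_id", "visit_date", "note_type", "text")
                %in% names(notes)))
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(notes))) {
    rec <- list(patient_id = notes$patient_id[i],
                note_id = notes$note_id[i],
                visit_date = as.character(notes$visit_date[i]),
                note_type = notes$note_type[i],
                text = notes$text[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_notes
#' @return `read_notes()` returns the notes data frame, `visit_date` as `Date`.
#' @export
read_notes <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  out <- data.frame(
    patient_id = vapply(recs, function(r) as.character(r$patient_id), character(1)),
    note_id = vapply(recs, function(r) as.character(r$note_id), character(1)),
    visit_date = as.Date(vapply(recs, function(r) as.character(r$visit_date), character(1))),
    note_type = vapply(recs, function(r) as.character(r$note_type), character(1)),
    text = vapply(recs, function(r) as.character(r$text), character(1)),
    stringsAsFactors = FALSE)
  out
}

#' Read and write per-patient outcome records
#'
#' Tab-separated, with header: `patient_id`, `death_date` (ISO-8601 or
#' empty when alive), `last_followup_date`.
#'
#' @param outcomes data frame with those columns (`death_date` may be `NA`).
#' @param path file path.
#' @export
write_outcomes <- function(outcomes, path) {
  df <- data.frame(patient_id = outcomes$patient_id,
                   death_date = ifelse(is.na(outcomes$death_date), "",
                                       as.character(outcomes$death_date)),
                   last_followup_date = as.character(outcomes$last_followup_date),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  data.frame(patient_id = df$patient_id,
             death_date = as.Date(ifelse(nzchar(df$death_date), df$death_date, NA)),
             last_followup_date = as.Date(df$last_followup_date),
             stringsAsFactors = FALSE)
}

#' Persist a note-vector table
#'
#' The matrix is stored as little-endian doubles in row-major note order in
#' `<path>.bin`, with a JSON sidecar `<path>.json` giving the dimension and
#' the row index (note_id to row, 1-based).
#'
#' @param vectors numeric matrix, one row per note, rownames = note ids.
#' @param path base path (without extension).
#' @export
write_note_vectors <- function(vectors, path) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  bin <- paste0(path, ".bin")
  con <- file(bin, open = "wb")
  writeBin(as.numeric(t(vectors)), con, size = 8, endian = "little")
  close(con)
  idx <- list(dim = ncol(vectors), n = nrow(vectors),
              note_ids = rownames(vectors))
  writeLines(jsonlite::toJSON(idx, auto_unbox = TRUE), paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_note_vectors
#' @export
read_note_vectors <- function(path) {
  idx <- jsonlite::fromJSON(paste0(path, ".json"))
  con <- file(paste0(path, ".bin"), open = "rb")
  x <- readBin(con, what = "numeric", n = idx$n * idx$dim, size = 8,
               endian = "little")
  close(con)
  m <- matrix(x, nrow = idx$n, ncol = idx$dim, byrow = TRUE)
  rownames(m) <- idx$note_ids
  m
}

#' Write a condensed or mapped corpus as JSON-lines
#'
#' One object per line: `note_id`, `tokens` (array). Mapped notes also carry
#' `mapped` (positions, spans, controlled terms, matched tokens).
#'
#' @param corpus a `condensed_corpus` or `mapped_corpus`.
#' @param path file path.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  ids <- names(corpus)
  for (i in seq_along(corpus)) {
    x <- corpus[[i]]
    rec <- if (inherits(x, "mapped_note")) {
      list(note_id = ids[i], tokens = x$tokens, mapped = x$mapped)
    } else {
      list(note_id = ids[i], tokens = x)
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, dataframe = "columns"),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  out <- lapply(recs, function(r) {
    if (!is.null(r$mapped)) {
      structure(list(tokens = as.character(unlist(r$tokens)),
                     mapped = data.frame(pos = as.integer(unlist(r$mapped$pos)),
                                         span = as.integer(unlist(r$mapped$span)),
                                         cterm = as.character(unlist(r$mapped$cterm)),
                                         matched = as.character(unlist(r$mapped$matched)),
                                         stringsAsFactors = FALSE)),
                class = "mapped_note")
    } else {
      as.character(unlist(r$tokens))
    }
  })
  names(out) <- vapply(recs, function(r) as.character(r$note_id), character(1))
  if (length(out) == 0L) return(structure(out, class = "condensed_corpus"))
  cls <- if (inherits(out[[1]], "mapped_note")) "mapped_corpus" else "condensed_corpus"
  structure(out, class = cls)
}
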