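#' Extract highlighted controlled-term findings from a note
#'
#' For every controlled-term occurrence recorded in the mapped note, locates
#' the matched surface form in the original (pre-condensed) text and returns
#' a snippet of up to `window` raw words on each side with the match
#' bracketed. Raw words are matched against the condensed surface tokens by
#' applying the same normalization (lowercase, number conversion, stemming);
#' intervening stopwords are allowed inside multi-word matches. Snippets are
#' deduplicated per (controlled term, snippet).
#'
#' @param raw_text the original note text.
#' @param mapped a `mapped_note` for that text.
#' @param window raw words kept on each side; default 5.
#' @return data frame: cterm, surface, snippet (possibly 0 rows).
#' @export
extract_findings <- function(raw_text, mapped, window = 5L) {
  empty <- data.frame(cterm = character(0), surface = character(0),
                      snippet = character(0), stringsAsFactors = FALSE)
  if (!inherits(mapped, "mapped_note") || nrow(mapped$mapped) == 0L)
    return(empty)
  raw <- strsplit(trimws(raw_text), "\\s+")[[1]]
  if (length(raw) == 0L) return(empty)
  norm <- vapply(raw, function(w) {
    t <- tokenize(w)
    if (length(t) == 0L) return("")
    t <- t[1]
    if (grepl("^[0-9]+$", t)) t <- int_to_token(as.integer(t))
    porter_stem(t)
  }, character(1), USE.NAMES = FALSE)
  is_stop <- norm %in% porter_stem(default_stoplist()) |
    vapply(raw, function(w) {
      t <- tokenize(w)
      length(t) > 0L && t[1] %in% default_stoplist()
    }, logical(1), USE.NAMES = FALSE)

  out <- vector("list", nrow(mapped$mapped))
  cursor <- 1L
  n <- length(raw)
  for (k in seq_len(nrow(mapped$mapped))) {
    key <- strsplit(mapped$mapped$matched[k], " ", fixed = TRUE)[[1]]
    hit <- find_span(norm, is_stop, key, cursor, max_extra = 4L)
    if (is.null(hit)) {
      # restart from the beginning in case condensed order diverged
      hit <- find_span(norm, is_stop, key, 1L, max_extra = 4L)
      if (is.null(hit)) next
    }
    lo <- max(1L, hit[1] - window); hi <- min(n, hit[2] + window)
    snippet <- paste(c(raw[seq(lo, hit[1] - 1L)[seq_len(max(0, hit[1] - lo))]],
                       "[", raw[hit[1]:hit[2]], "]",
                       raw[seq(hit[2] + 1L, hi)[seq_len(max(0, hi - hit[2]))]]),
                     collapse = " ")
    out[[k]] <- data.frame(cterm = mapped$mapped$cterm[k],
                           surface = mapped$mapped$matched[k],
                           snippet = snippet, stringsAsFactors = FALSE)
    cursor <- hit[2] + 1L
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty)
  out[!duplicated(out[, c("cterm", "snippet")]), , drop = FALSE]
}

# find key tokens in order in norm, starting at `from`; stopword tokens may
# intervene; total span at most length(key) + max_extra
find_span <- function(norm, is_stop, key, from, max_extra = 4L) {
  n <- length(norm)
  kl <- length(key)
  i <- from
  while (i <= n - kl + 1L) {
    if (norm[i] == key[1]) {
      j <- i; ki <- 1L; extra <- 0L
      while (j <= n && ki <= kl && extra <= max_extra) {
        if (norm[j] == key[ki]) {
          ki <- ki + 1L; j <- j + 1L
        } else if (is_stop[j] || norm[j] == "") {
          extra <- extra + 1L; j <- j + 1L
        } else break
      }
      if (ki > kl) return(c(i, j - 1L))
    }
    i <- i + 1L
  }
  NULL
}

#' Build a per-patient longitudinal summary
#'
#' Joins a patient's predictions to their notes, extracts the highlighted
#' controlled-term findings per visit, and carries the visit (note) type.
#'
#' @param pred predictions data frame (or `prediction_set`).
#' @param notes notes data frame.
#' @param dict a `term_dictionary`.
#' @param patient_id the patient to summarize.
#' @param collocations optional `collocation_model` applied before mapping.
#' @return list of class `patient_summary`: `patient_id`, `curve` (data
#'   frame: visit_index, visit_date, p_surv, true_label, note_type), and
#'   `findings` (list per visit of finding data frames).
#' @export
build_summary <- function(pred, notes, dict, patient_id,
                          collocations = NULL) {
  if (inherits(pred, "prediction_set")) pred <- pred$predictions
  pr <- pred[pred$patient_id == patient_id, , drop = FALSE]
  if (nrow(pr) == 0L) stop("no predictions for patient ", patient_id)
  missing_notes <- setdiff(pr$note_id, notes$note_id)
  if (length(missing_notes) > 0L)
    stop("prediction note id(s) not found in notes: ",
         paste(missing_notes, collapse = ", "))
  nt <- notes[match(pr$note_id, notes$note_id), ]
  curve <- data.frame(visit_index = pr$visit_index,
                      visit_date = pr$visit_date,
                      p_surv = pr$p_survival,
                      true_label = pr$true_label,
                      note_type = nt$note_type,
                      note_id = pr$note_id,
                      stringsAsFactors = FALSE)
  findings <- vector("list", nrow(pr))
  for (i in seq_len(nrow(pr))) {
    toks <- condense(nt$text[i], nt$visit_date[i])
    if (!is.null(collocations)) toks <- apply_collocations(toks, collocations)
    mapped <- map_terms(toks, dict)
    findings[[i]] <- extract_findings(nt$text[i], mapped)
  }
  names(findings) <- pr$note_id
  structure(list(patient_id = patient_id, curve = curve, findings = findings),
            class = "patient_summary")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

summary_svg <- function(curve, width = 680, height = 240) {
  n <- nrow(curve)
  pad <- 30
  xs <- function(i) pad + (i - 1) / max(1, n - 1) * (width - 2 * pad)
  ys <- function(p) height - pad - p * (height - 2 * pad)
  fmt <- function(v) formatC(v, format = "f", digits = 2)
  pred_pts <- paste(fmt(xs(seq_len(n))), fmt(ys(curve$p_surv)),
                    sep = ",", collapse = " ")
  truth <- ifelse(curve$true_label == "POS", 1,
                  ifelse(curve$true_label == "NEG", 0, NA))
  ok <- !is.na(truth)
  truth_pts <- paste(fmt(xs(which(ok))), fmt(ys(truth[ok])),
                     sep = ",", collapse = " ")
  paste0(
    '<svg width="', width, '" height="', height,
    '" viewBox="0 0 ', width, " ", height, '">',
    '<rect width="100%" height="100%" fill="white"/>',
    '<line x1="', pad, '" y1="', ys(0), '" x2="', width - pad, '" y2="', ys(0),
    '" stroke="#999"/>',
    '<line x1="', pad, '" y1="', ys(0), '" x2="', pad, '" y2="', ys(1),
    '" stroke="#999"/>',
    '<text x="4" y="', ys(1) + 4, '" font-size="10">1.0</text>',
    '<text x="4" y="', ys(0) + 4, '" font-size="10">0.0</text>',
    if (any(ok)) paste0('<polyline points="', truth_pts,
                        '" fill="none" stroke="#2b6cb0" stroke-width="2"/>') else "",
    '<polyline points="', pred_pts,
    '" fill="none" stroke="#2f855a" stroke-width="2"/>',
    "</svg>")
}

#' Render a patient summary as a standalone HTML report
#'
#' Self-contained document: the survival-probability curve (green) against
#' the ground-truth labels (blue, survival-positive = 1, survival-negative
#' = 0), and per-visit expandable sections listing the visit type and the
#' highlighted controlled-term findings. Output is a pure function of the
#' summary — no timestamps — so rendering is byte-stable.
#'
#' @param summary a `patient_summary`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
render_report <- function(summary, path) {
  cv <- summary$curve
  blocks <- vapply(seq_len(nrow(cv)), function(i) {
    f <- summary$findings[[cv$note_id[i]]]
    items <- if (is.null(f) || nrow(f) == 0L) {
      "<li><em>no controlled-term findings</em></li>"
    } else {
      paste0("<li><b>", html_escape(f$cterm), "</b>: ",
             html_escape(f$snippet), "</li>", collapse = "")
    }
    paste0("<details><summary>Visit ", cv$visit_index[i], " — ",
           html_escape(as.character(cv$visit_date[i])), " — ",
           html_escape(cv$note_type[i]), " — p(surv) ",
           formatC(cv$p_surv[i], format = "f", digits = 3), " — ",
           html_escape(cv$true_label[i]),
           "</summary><ul>", items, "</ul></details>")
  }, character(1))
  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\"/><title>Patient ",
    html_escape(summary$patient_id), "</title><style>",
    "body{font-family:sans-serif;max-width:760px;margin:2em auto;}",
    "details{margin:0.3em 0;border-left:3px solid #ddd;padding-left:0.6em;}",
    "</style></head><body><h1>Patient ", html_escape(summary$patient_id),
    "</h1><p>Predicted probability of surviving beyond 3 months (green) ",
    "against ground truth (blue; survival-positive = 1).</p>",
    summary_svg(cv), paste0(blocks, collapse = "\n"),
    "</body></html>")
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}

#' Render reports for several patients plus an index page
#'
#' @param pred predictions (`prediction_set` or data frame).
#' @param notes notes data frame.
#' @param dict a `term_dictionary`.
#' @param patients character vector of patient ids.
#' @param out_dir output directory.
#' @param collocations optional `collocation_model`.
#' @return invisible vector of written paths.
#' @export
render_cohort_reports <- function(pred, notes, dict, patients, out_dir,
                                  collocations = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (pid in patients) {
    s <- build_summary(pred, notes, dict, pid, collocations)
    p <- file.path(out_dir, paste0("patient_", pid, ".html"))
    render_report(s, p)
    js <- file.path(out_dir, paste0("patient_", pid, ".json"))
    writeLines(jsonlite::toJSON(list(patient_id = s$patient_id,
                                     curve = s$curve,
                                     findings = s$findings),
                                auto_unbox = TRUE, digits = NA,
                                dataframe = "rows"), js)
    paths <- c(paths, p, js)
  }
  idx <- paste0(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\"/>",
    "<title>Patient reports</title></head><body><h1>Patient reports</h1><ul>",
    paste0("<li><a href=\"patient_", html_escape(patients), ".html\">",
           html_escape(patients), "</a></li>", collapse = ""),
    "</ul></body></html>")
  ip <- file.path(out_dir, "index.html")
  writeLines(idx, ip, useBytes = TRUE)
  invisible(c(paths, ip))
}
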