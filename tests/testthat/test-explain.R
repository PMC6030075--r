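test_that("notes without mapped terms yield no findings", {
  note <- hand_mapped_note(c("routine", "exam"), integer(0))
  expect_equal(nrow(extract_findings("routine exam today", note)), 0L)
})

test_that("snippets truncate at note boundaries and bracket the match", {
  dict <- load_dictionary(tiny_dict_file(list(lesion = "LESION")))
  text <- "a small lesion in the left lower lobe near the hilum"
  toks <- condense(text, as.Date("2020-01-01"))
  mapped <- map_terms(toks, dict)
  f <- extract_findings(text, mapped)
  expect_equal(nrow(f), 1L)
  expect_equal(f$cterm, "LESION")
  expect_true(grepl("\\[ lesion \\]", f$snippet))
  # 5 words kept on each side at most; left side truncated at note start
  expect_match(f$snippet, "^a small \\[ lesion \\]")
})

test_that("findings agree with a brute-force raw-window slicer", {
  dict <- load_dictionary(example_dictionary_path())
  coh <- generate_cohort(cohort_config(n_patients = 8, seed = 13))
  idx <- seq_len(min(20, nrow(coh$notes)))
  for (i in idx) {
    text <- coh$notes$text[i]
    toks <- condense(text, coh$notes$visit_date[i])
    mapped <- map_terms(toks, dict)
    f <- extract_findings(text, mapped)
    if (nrow(f) == 0L) next
    raw <- strsplit(trimws(text), "\\s+")[[1]]
    for (r in seq_len(nrow(f))) {
      open <- regexpr("\\[", f$snippet[r])
      before <- strsplit(trimws(substr(f$snippet[r], 1, open - 1)),
                         "\\s+")[[1]]
      before <- before[nzchar(before)]
      after <- strsplit(trimws(sub(".*\\] ?", "", f$snippet[r])),
                        "\\s+")[[1]]
      after <- after[nzchar(after)]
      expect_lte(length(before), 5L)
      expect_lte(length(after), 5L)
      # the de-bracketed snippet must be a contiguous slice of the raw words
      words <- strsplit(gsub("\\[ | \\]", "", f$snippet[r]), " ")[[1]]
      m <- length(words)
      found <- FALSE
      for (j in seq_len(length(raw) - m + 1)) {
        if (identical(raw[j:(j + m - 1)], words)) {
          found <- TRUE
          # window is maximal: either 5 words kept or truncated at an edge
          if (length(before) < 5) expect_equal(j, 1L)
          if (length(after) < 5) expect_equal(j + m - 1L, length(raw))
          break
        }
      }
      expect_true(found, info = f$snippet[r])
    }
  }
})

test_that("every snippet's surface maps to the controlled term it is listed under", {
  dict <- load_dictionary(example_dictionary_path())
  coh <- generate_cohort(cohort_config(n_patients = 5, seed = 17))
  for (i in 1:10) {
    text <- coh$notes$text[i]
    toks <- condense(text, coh$notes$visit_date[i])
    f <- extract_findings(text, map_terms(toks, dict))
    for (r in seq_len(nrow(f))) {
      remap <- map_terms(strsplit(f$surface[r], " ")[[1]], dict)
      expect_true(f$cterm[r] %in% remap$tokens)
    }
  }
})

test_that("patient summaries join predictions, notes and findings", {
  fit <- small_trained_pipeline()
  pred <- fit$predictions$predictions
  pid <- pred$patient_id[1]
  dict <- load_dictionary(example_dictionary_path())
  s <- build_summary(pred, fit$cohort$notes, dict, pid,
                     collocations = fit$collocations)
  n_real <- sum(pred$patient_id == pid)
  expect_equal(nrow(s$curve), n_real)
  expect_equal(s$curve$p_surv,
               pred$p_survival[pred$patient_id == pid])
  expect_equal(length(s$findings), n_real)
  # unmatched note ids are a join error listing the ids
  broken <- pred[pred$patient_id == pid, ]
  broken$note_id[1] <- "NOPE01"
  expect_error(build_summary(broken, fit$cohort$notes, dict, pid), "NOPE01")
})

test_that("rendering is deterministic and encodes labels as 1 and 0", {
  fit <- small_trained_pipeline()
  pred <- fit$predictions$predictions
  pid <- pred$patient_id[1]
  dict <- load_dictionary(example_dictionary_path())
  s <- build_summary(pred, fit$cohort$notes, dict, pid)
  f1 <- tempfile(fileext = ".html"); f2 <- tempfile(fileext = ".html")
  render_report(s, f1); render_report(s, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  html <- paste(readLines(f1, warn = FALSE), collapse = "\n")
  expect_match(html, "polyline")           # curve present
  expect_match(html, "<details>")          # expandable visits
  expect_match(html, pid, fixed = TRUE)
  # ground truth drawn at 1 for POS and 0 for NEG via the y scale
  expect_match(html, "#2b6cb0")            # truth colour
  expect_match(html, "#2f855a")            # prediction colour
})

test_that("an empty-findings summary still renders the curve", {
  curve <- data.frame(visit_index = 1:3,
                      visit_date = as.Date("2020-01-01") + 1:3,
                      p_surv = c(0.9, 0.8, 0.7),
                      true_label = c("POS", "POS", "NEG"),
                      note_type = "oncology",
                      note_id = c("a", "b", "c"), stringsAsFactors = FALSE)
  s <- structure(list(patient_id = "PX", curve = curve,
                      findings = stats::setNames(
                        rep(list(data.frame()), 3), c("a", "b", "c"))),
                 class = "patient_summary")
  path <- tempfile(fileext = ".html")
  render_report(s, path)
  html <- paste(readLines(path, warn = FALSE), collapse = "\n")
  expect_match(html, "no controlled-term findings")
  expect_match(html, "polyline")
})

test_that("cohort rendering writes one report per patient plus an index", {
  fit <- small_trained_pipeline()
  pred <- fit$predictions$predictions
  pids <- unique(pred$patient_id)[1:3]
  dict <- load_dictionary(example_dictionary_path())
  dir <- tempfile()
  render_cohort_reports(pred, fit$cohort$notes, dict, pids, dir)
  for (p in pids) {
    expect_true(file.exists(file.path(dir, paste0("patient_", p, ".html"))))
    expect_true(file.exists(file.path(dir, paste0("patient_", p, ".json"))))
  }
  idx <- paste(readLines(file.path(dir, "index.html"), warn = FALSE),
               collapse = "")
  for (p in pids) expect_match(idx, p, fixed = TRUE)
})
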