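test_that("the survival rule labels visits by date arithmetic", {
  v <- as.Date("2015-01-01")
  expect_equal(label_visit(v, v + 50, v + 50), "NEG")     # death 50 days after
  expect_equal(label_visit(v, v + 100, v + 100), "POS")   # death 100 days after
  expect_equal(label_visit(v, as.Date(NA), v + 30), "UNDEFINED")  # short follow-up
  expect_equal(label_visit(v, as.Date(NA), v + 92), "POS")
  expect_equal(label_visit(v, v + 91, v + 91), "NEG")     # boundary: exactly 91
  expect_error(label_visit(v, as.Date(NA), v - 1), "follow-up")
})

make_vectors <- function(notes, D = 3) {
  m <- matrix(seq_len(nrow(notes) * D), nrow(notes), D)
  rownames(m) <- notes$note_id
  m
}

toy_notes <- function(n, pid = "P1", start = as.Date("2014-01-01"), gap = 10) {
  data.frame(patient_id = pid,
             note_id = sprintf("%s-N%04d", pid, seq_len(n)),
             visit_date = start + gap * (seq_len(n) - 1),
             note_type = "oncology", text = "x", stringsAsFactors = FALSE)
}

test_that("short sequences are right-padded with zero vectors and PAD labels", {
  notes <- toy_notes(3)
  outcomes <- data.frame(patient_id = "P1", death_date = as.Date(NA),
                         last_followup_date = max(notes$visit_date) + 500)
  ds <- build_sequences(make_vectors(notes), notes, outcomes, max_len = 5)
  expect_equal(dim(ds$x), c(1, 5, 3))
  expect_equal(ds$mask[1, ], c(1, 1, 1, 0, 0))
  expect_equal(ds$y[1, ], c(1, 1, 1, 3, 3))      # POS POS POS PAD PAD
  expect_equal(ds$x[1, 4, ], c(0, 0, 0))
})

test_that("long sequences keep the most recent visits", {
  notes <- toy_notes(1200, gap = 1)
  outcomes <- data.frame(patient_id = "P1", death_date = as.Date(NA),
                         last_followup_date = max(notes$visit_date) + 500)
  ds <- build_sequences(make_vectors(notes), notes, outcomes, max_len = 1000)
  # first kept visit is original index 200 (0-based), i.e. note 201
  expect_equal(ds$manifest$P1$note_id[1], notes$note_id[201])
  expect_equal(sum(ds$mask), 1000)
})

test_that("a sequence exactly at max_len is neither padded nor truncated", {
  notes <- toy_notes(6)
  outcomes <- data.frame(patient_id = "P1", death_date = as.Date(NA),
                         last_followup_date = max(notes$visit_date) + 500)
  ds <- build_sequences(make_vectors(notes), notes, outcomes, max_len = 6)
  expect_equal(sum(ds$mask), 6)
  expect_equal(ds$manifest$P1$note_id, notes$note_id)
})

test_that("patients with fewer than two visits are dropped with a warning", {
  notes <- rbind(toy_notes(4, "P1"), toy_notes(1, "P2"))
  outcomes <- data.frame(patient_id = c("P1", "P2"),
                         death_date = as.Date(c(NA, NA)),
                         last_followup_date = max(notes$visit_date) + 500)
  expect_warning(ds <- build_sequences(make_vectors(notes), notes, outcomes,
                                       max_len = 5), "fewer than 2")
  expect_equal(ds$patient_id, "P1")
})

test_that("same-day visits stay separate timesteps ordered by note id", {
  notes <- toy_notes(4)
  notes$visit_date[2] <- notes$visit_date[1]
  outcomes <- data.frame(patient_id = "P1", death_date = as.Date(NA),
                         last_followup_date = max(notes$visit_date) + 500)
  ds <- build_sequences(make_vectors(notes), notes, outcomes, max_len = 4)
  expect_equal(ds$manifest$P1$note_id, sort(notes$note_id))
})

test_that("censored visits are labelled UNDEFINED but keep their inputs", {
  notes <- toy_notes(3, gap = 40)
  outcomes <- data.frame(patient_id = "P1", death_date = as.Date(NA),
                         last_followup_date = max(notes$visit_date) + 60)
  ds <- build_sequences(make_vectors(notes), notes, outcomes, max_len = 3)
  expect_equal(ds$y[1, ], c(1, 1, 4))  # last visit is censored
  expect_false(all(ds$x[1, 3, ] == 0))
  expect_equal(ds$mask[1, 3], 1L)
})

test_that("real timesteps never carry the all-zeros vector", {
  fit <- small_trained_pipeline()
  ds <- fit$dataset
  real <- which(ds$mask == 1L, arr.ind = TRUE)
  norms <- vapply(seq_len(nrow(real)), function(k)
    sum(abs(ds$x[real[k, 1], real[k, 2], ])), numeric(1))
  expect_true(all(norms > 0))
  pad <- which(ds$mask == 0L, arr.ind = TRUE)
  if (nrow(pad) > 0) {
    pn <- vapply(seq_len(nrow(pad)), function(k)
      sum(abs(ds$x[pad[k, 1], pad[k, 2], ])), numeric(1))
    expect_true(all(pn == 0))
  }
})

test_that("patient-level splits are deterministic, disjoint and exhaustive", {
  notes <- do.call(rbind, lapply(sprintf("P%03d", 1:100), toy_notes, n = 3))
  outcomes <- data.frame(patient_id = sprintf("P%03d", 1:100),
                         death_date = as.Date(NA),
                         last_followup_date = as.Date("2014-01-21") + 500)
  ds <- build_sequences(make_vectors(notes), notes, outcomes, max_len = 3)
  sp <- split_cohort(ds, c(0.8, 0.1, 0.1), seed = 4)
  expect_equal(length(sp$train$patient_id), 80L)
  expect_equal(length(sp$validation$patient_id), 10L)
  expect_equal(length(sp$test$patient_id), 10L)
  all_ids <- c(sp$train$patient_id, sp$validation$patient_id,
               sp$test$patient_id)
  expect_equal(sort(all_ids), sort(ds$patient_id))
  expect_equal(anyDuplicated(all_ids), 0L)
  sp2 <- split_cohort(ds, c(0.8, 0.1, 0.1), seed = 4)
  expect_identical(sp$train$patient_id, sp2$train$patient_id)
  expect_error(split_cohort(ds, c(1.2, -0.1, -0.1)), "fraction")
  expect_error(split_cohort(ds, c(0.5, 0.4, 0.2)), "sum to 1")
})

test_that("un-padding then re-padding is the identity", {
  fit <- small_trained_pipeline()
  ds <- fit$dataset
  i <- 1L
  k <- sum(ds$mask[i, ])
  # un-pad: extract the real timesteps, rebuild a 1-patient dataset
  man <- ds$manifest[[i]]
  vec <- matrix(ds$x[i, seq_len(k), ], k, ds$D)
  rownames(vec) <- man$note_id
  notes1 <- fit$cohort$notes[fit$cohort$notes$note_id %in% man$note_id, ]
  ds1 <- build_sequences(vec, notes1, fit$cohort$outcomes,
                         max_len = ds$max_len)
  expect_equal(ds1$x[1, , ], ds$x[i, , ])
  expect_equal(ds1$y[1, ], ds$y[i, ])
  expect_equal(ds1$mask[1, ], ds$mask[i, ])
})

test_that("a dataset round-trips through its on-disk form", {
  notes <- toy_notes(4)
  outcomes <- data.frame(patient_id = "P1", death_date = as.Date(NA),
                         last_followup_date = max(notes$visit_date) + 500)
  ds <- build_sequences(make_vectors(notes), notes, outcomes, max_len = 6)
  dir <- tempfile()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$x, ds$x)
  expect_equal(back$y, ds$y)
  expect_equal(back$mask, ds$mask)
  expect_equal(back$manifest$P1$note_id, ds$manifest$P1$note_id)
  expect_equal(back$manifest$P1$visit_date, ds$manifest$P1$visit_date)
})
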