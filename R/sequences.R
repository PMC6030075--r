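#' Label a visit by the 3-month survival rule
#'
#' Survival-negative if a death is recorded no more than `horizon_days`
#' after the visit; survival-positive if death (or follow-up, for survivors)
#' lies beyond the horizon; undefined (censored) if the patient is alive but
#' follow-up ends within the horizon. Vectorized over visits.
#'
#' @param visit_date `Date` vector.
#' @param death_date `Date` vector (NA when alive), recycled.
#' @param last_followup_date `Date` vector, recycled.
#' @param horizon_days the survival horizon; default 91 (about 3 months).
#' @return character vector: "POS", "NEG" or "UNDEFINED".
#' @export
label_visit <- function(visit_date, death_date, last_followup_date,
                        horizon_days = 91L) {
  stopifnot(horizon_days > 0L)
  visit_date <- as.Date(visit_date)
  death_date <- as.Date(death_date)
  last_followup_date <- as.Date(last_followup_date)
  if (any(visit_date > last_followup_date, na.rm = TRUE))
    stop("visit date after last follow-up date: inconsistent outcome record")
  dead <- !is.na(death_date)
  gap_death <- as.integer(death_date - visit_date)
  gap_fu <- as.integer(last_followup_date - visit_date)
  out <- rep("UNDEFINED", length(visit_date))
  out[dead & gap_death <= horizon_days] <- "NEG"
  out[dead & gap_death > horizon_days] <- "POS"
  out[!dead & gap_fu > horizon_days] <- "POS"
  out
}

# integer label codes used inside datasets
.lab_codes <- c(POS = 1L, NEG = 2L, PAD = 3L, UNDEFINED = 4L)

#' Build padded per-patient sequences
#'
#' Orders each patient's notes by visit date (ties broken by note id), drops
#' patients with fewer than 2 visits (with a warning), keeps the `max_len`
#' most recent visits when a sequence is longer, and right-pads shorter
#' sequences with zero vectors and PAD labels. Censored visits (outcome
#' unknowable within the horizon) are kept as inputs but labelled UNDEFINED;
#' they get zero loss weight in training and are excluded from evaluation.
#'
#' @param vectors note-vector matrix (rownames = note ids).
#' @param notes notes data frame.
#' @param outcomes outcomes data frame.
#' @param max_len fixed sequence length; default 1000.
#' @param horizon_days survival horizon; default 91.
#' @return object of class `sequence_dataset`: list with `x` (array
#'   n_patients x max_len x D), `y` (integer matrix of label codes 1=POS,
#'   2=NEG, 3=PAD, 4=UNDEFINED), `mask` (1 = real visit), `patient_id`, and
#'   `manifest` (per-patient data frame of visit_date/note_id kept).
#' @export
build_sequences <- function(vectors, notes, outcomes, max_len = 1000L,
                            horizon_days = 91L) {
  stopifnot(is.matrix(vectors), max_len >= 2L)
  missing_vec <- setdiff(notes$note_id, rownames(vectors))
  if (length(missing_vec) > 0L)
    stop("notes without vectors: ", paste(utils::head(missing_vec, 5), collapse = ", "))
  D <- ncol(vectors)
  oc <- outcomes[match(notes$patient_id, outcomes$patient_id), ]
  lab <- label_visit(notes$visit_date, oc$death_date, oc$last_followup_date,
                     horizon_days)

  ord <- order(notes$patient_id, notes$visit_date, notes$note_id)
  notes <- notes[ord, ]; lab <- lab[ord]
  split_idx <- split(seq_len(nrow(notes)), notes$patient_id)

  keep <- vapply(split_idx, length, integer(1)) >= 2L
  if (any(!keep))
    warning(sum(!keep), " patient(s) with fewer than 2 visits dropped")
  split_idx <- split_idx[keep]

  n <- length(split_idx)
  x <- array(0, dim = c(n, max_len, D))
  y <- matrix(.lab_codes[["PAD"]], nrow = n, ncol = max_len)
  mask <- matrix(0L, nrow = n, ncol = max_len)
  manifest <- vector("list", n)
  pids <- names(split_idx)

  for (i in seq_len(n)) {
    idx <- split_idx[[i]]
    if (length(idx) > max_len)  # keep the most recent visits
      idx <- idx[(length(idx) - max_len + 1L):length(idx)]
    k <- length(idx)
    x[i, seq_len(k), ] <- vectors[notes$note_id[idx], , drop = FALSE]
    y[i, seq_len(k)] <- .lab_codes[lab[idx]]
    mask[i, seq_len(k)] <- 1L
    manifest[[i]] <- data.frame(visit_date = notes$visit_date[idx],
                                note_id = notes$note_id[idx],
                                label = lab[idx], stringsAsFactors = FALSE)
  }
  names(manifest) <- pids
  structure(list(x = x, y = y, mask = mask, patient_id = pids,
                 manifest = manifest, max_len = as.integer(max_len),
                 D = D, horizon_days = as.integer(horizon_days)),
            class = "sequence_dataset")
}

#' @export
print.sequence_dataset <- function(x, ...) {
  cat("sequence_dataset:", length(x$patient_id), "patients x", x$max_len,
      "timesteps x", x$D, "dims;", sum(x$mask), "real visits\n")
  invisible(x)
}

#' Subset a sequence dataset by patient index
#' @param ds a `sequence_dataset`.
#' @param idx integer or logical patient index.
#' @return a `sequence_dataset` containing those patients.
#' @export
subset_dataset <- function(ds, idx) {
  structure(list(x = ds$x[idx, , , drop = FALSE],
                 y = ds$y[idx, , drop = FALSE],
                 mask = ds$mask[idx, , drop = FALSE],
                 patient_id = ds$patient_id[idx],
                 manifest = ds$manifest[idx],
                 max_len = ds$max_len, D = ds$D,
                 horizon_days = ds$horizon_days),
            class = "sequence_dataset")
}

#' Split a dataset into train / validation / test at patient level
#'
#' Patients (never visits) are shuffled with the given seed and partitioned
#' by the three fractions, which must sum to 1. Splits are disjoint and
#' exhaustive.
#'
#' @param ds a `sequence_dataset`.
#' @param fractions numeric length-3 vector (train, validation, test).
#' @param seed integer seed.
#' @return named list of `sequence_dataset`: `train`, `validation`, `test`.
#' @export
split_cohort <- function(ds, fractions = c(0.8, 0.05, 0.15), seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0) || any(fractions >= 1))
    stop("fractions must be three values in (0,1)")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- length(ds$patient_id)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  perm <- sample.int(n)
  n_tr <- round(fractions[1] * n)
  n_va <- round(fractions[2] * n)
  n_tr <- min(n_tr, n); n_va <- min(n_va, n - n_tr)
  list(train = subset_dataset(ds, perm[seq_len(n_tr)]),
       validation = subset_dataset(ds, perm[n_tr + seq_len(n_va)]),
       test = subset_dataset(ds, perm[setdiff(seq_len(n), seq_len(n_tr + n_va))]))
}

#' Persist / load a sequence dataset
#'
#' Arrays are stored as little-endian doubles/integers plus a JSON manifest.
#'
#' @param ds a `sequence_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "x.bin"), "wb")
  writeBin(as.numeric(ds$x), con, size = 8, endian = "little"); close(con)
  con <- file(file.path(dir, "y.bin"), "wb")
  writeBin(as.integer(ds$y), con, size = 4, endian = "little"); close(con)
  con <- file(file.path(dir, "mask.bin"), "wb")
  writeBin(as.integer(ds$mask), con, size = 4, endian = "little"); close(con)
  meta <- list(n = length(ds$patient_id), max_len = ds$max_len, D = ds$D,
               horizon_days = ds$horizon_days, patient_id = ds$patient_id,
               manifest = lapply(ds$manifest, function(m)
                 list(visit_date = as.character(m$visit_date),
                      note_id = m$note_id, label = m$label)))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                             simplifyDataFrame = FALSE)
  n <- meta$n; T <- meta$max_len; D <- meta$D
  con <- file(file.path(dir, "x.bin"), "rb")
  x <- array(readBin(con, "numeric", n * T * D, size = 8, endian = "little"),
             dim = c(n, T, D)); close(con)
  con <- file(file.path(dir, "y.bin"), "rb")
  y <- matrix(readBin(con, "integer", n * T, size = 4, endian = "little"),
              nrow = n); close(con)
  con <- file(file.path(dir, "mask.bin"), "rb")
  mask <- matrix(readBin(con, "integer", n * T, size = 4, endian = "little"),
                 nrow = n); close(con)
  manifest <- lapply(meta$manifest, function(m)
    data.frame(visit_date = as.Date(unlist(m$visit_date)),
               note_id = as.character(unlist(m$note_id)),
               label = as.character(unlist(m$label)),
               stringsAsFactors = FALSE))
  names(manifest) <- unlist(meta$patient_id)
  structure(list(x = x, y = y, mask = mask,
                 patient_id = as.character(unlist(meta$patient_id)),
                 manifest = manifest, max_len = T, D = D,
                 horizon_days = meta$horizon_days),
            class = "sequence_dataset")
}
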