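#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the structure of a longitudinal metastatic-cancer
#' EMR corpus: multiple note types, irregular visit gaps, a heavy-tailed
#' (log-normal) visits-per-patient distribution, roughly 80% survival-
#' positive visit labels, and a plantable textual signal — fatal-signal
#' phrases built from controlled-term surface forms — inserted into the
#' notes of dying patients within their last 90 days at rate
#' `signal_strength`.
#'
#' @param n_patients number of patients (>= 1).
#' @param visits_law law for visits per patient: `"geometric"` (the default;
#'   2 + geometric with mean `visits_mean`, memoryless, so a visit's
#'   position in the record carries no information about how close the
#'   record end — and hence a death — is) or `"lognormal"` (heavy-tailed;
#'   closer to real visit-count distributions, but position then predicts
#'   the label even without any textual signal).
#' @param visits_mean mean visits per patient under the geometric law.
#' @param visits_meanlog,visits_sdlog log-normal law parameters (rounded,
#'   clamped to at least 2 visits).
#' @param max_visits cap on visits per patient; default 1200 so that
#'   sequence-truncation paths are exercised.
#' @param note_types labels sampled per note.
#' @param gap_meanlog,gap_sdlog log-normal law for the day gap between
#'   consecutive visits (rounded to a positive integer).
#' @param same_day_prob probability that a visit shares its date with the
#'   previous one (several providers seeing the patient the same day).
#' @param signal_strength probability in \[0,1\] that a note within 90 days
#'   of death carries a fatal-signal phrase.
#' @param positive_fraction_target target fraction in (0,1) of
#'   survival-positive visit labels; default 0.8.
#' @param censor_fraction fraction of surviving patients whose follow-up
#'   ends within the labelling horizon (their tail visits are censored).
#' @param seed integer RNG seed.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 200L,
                          visits_law = c("geometric", "lognormal"),
                          visits_mean = 8,
                          visits_meanlog = log(12), visits_sdlog = 1.0,
                          max_visits = 1200L,
                          note_types = c("oncology", "radiology", "inpatient"),
                          gap_meanlog = log(12), gap_sdlog = 0.8,
                          same_day_prob = 0.05,
                          signal_strength = 1.0,
                          positive_fraction_target = 0.8,
                          censor_fraction = 0.1,
                          seed = 1L) {
  chk <- function(ok, field, msg) if (!ok) stop("invalid cohort_config$", field, ": ", msg)
  visits_law <- match.arg(visits_law)
  chk(is.numeric(n_patients) && n_patients >= 1, "n_patients", "must be >= 1")
  chk(is.finite(visits_mean) && visits_mean > 2, "visits_mean", "must be > 2")
  chk(is.finite(visits_meanlog), "visits_meanlog", "must be finite")
  chk(is.finite(visits_sdlog) && visits_sdlog >= 0, "visits_sdlog", "must be >= 0")
  chk(max_visits >= 2, "max_visits", "must be >= 2")
  chk(length(note_types) >= 1, "note_types", "must be nonempty")
  chk(is.finite(gap_meanlog), "gap_meanlog", "must be finite")
  chk(is.finite(gap_sdlog) && gap_sdlog >= 0, "gap_sdlog", "must be >= 0")
  chk(same_day_prob >= 0 && same_day_prob <= 1, "same_day_prob", "must be in [0,1]")
  chk(signal_strength >= 0 && signal_strength <= 1, "signal_strength",
      "must be in [0,1]")
  chk(positive_fraction_target > 0 && positive_fraction_target < 1,
      "positive_fraction_target", "must be in (0,1)")
  chk(censor_fraction >= 0 && censor_fraction <= 1, "censor_fraction",
      "must be in [0,1]")
  structure(list(n_patients = as.integer(n_patients),
                 visits_law = visits_law, visits_mean = visits_mean,
                 visits_meanlog = visits_meanlog, visits_sdlog = visits_sdlog,
                 max_visits = as.integer(max_visits),
                 note_types = as.character(note_types),
                 gap_meanlog = gap_meanlog, gap_sdlog = gap_sdlog,
                 same_day_prob = same_day_prob,
                 signal_strength = signal_strength,
                 positive_fraction_target = positive_fraction_target,
                 censor_fraction = censor_fraction,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Fatal-signal surface terms planted by the generator
#'
#' The surface forms (all present in the bundled dictionary) that only occur
#' inside fatal-signal phrases. Tests and audits can grep note text for
#' these to count planted signals.
#'
#' @return character vector of surface terms/phrases.
#' @export
fatal_signal_terms <- function() {
  c("hospice", "palliative", "deteriorating", "decline", "unresponsive",
    "critical", "dnr", "comfort care")
}

.fatal_phrases <- c(
  "family meeting held and patient transitioned to hospice with comfort care measures",
  "rapid clinical decline noted patient visibly deteriorating",
  "condition now critical patient intermittently unresponsive dnr order discussed",
  "palliative care team consulted for end stage disease goals of care revisited"
)

.benign_fillers <- c(
  "patient", "seen", "clinic", "today", "routine", "followup", "visit",
  "reports", "feeling", "well", "overall", "status", "unchanged", "exam",
  "unremarkable", "continues", "current", "regimen", "tolerating",
  "treatment", "plan", "discussed", "labs", "reviewed", "within", "normal",
  "limits", "chest", "abdomen", "pelvis", "liver", "lung", "bone", "spine",
  "shows", "evidence", "disease", "findings", "compared", "prior", "study",
  "interval", "change", "appears", "noted", "right", "left", "lower",
  "upper", "lobe", "small", "large", "appetite", "weight", "energy",
  "performance", "good", "returns", "assessment", "impression"
)

.benign_qual <- c("stable", "mild", "moderate", "increased", "decrease",
                  "diffuse", "extensive")
.benign_symptom <- c("pain", "fatigue", "nausea", "dyspnea")
.benign_risk <- c("possible", "probable", "likely", "suspicious")
.benign_onco <- c("lesion", "nodule", "metastasis", "tumor", "chemotherapy",
                  "radiation", "scan", "imaging", "biopsy", "carcinoma")
.benign_family <- c("mother", "brother", "wife", "daughter", "husband")

# one benign note text; guaranteed to contain at least one dictionary
# surface form so every note vector has a controlled-term context
compose_benign_note <- function(visit_date) {
  pick <- function(pool, k = 1L) sample(pool, k, replace = TRUE)
  s1 <- paste(c(pick(.benign_fillers, 4L), pick(.benign_qual),
                pick(.benign_symptom)), collapse = " ")
  s2 <- switch(sample.int(4L, 1L),
    paste("imaging shows", pick(.benign_risk), pick(.benign_onco), "in the",
          pick(c("liver", "lung", "bone", "spine"))),
    paste("no evidence of progression on", pick(c("scan", "imaging"))),
    paste(pick(.benign_family), "present at visit", pick(.benign_onco),
          "plan reviewed"),
    paste("reported", sample.int(30L, 1L), "episodes of",
          pick(.benign_symptom), "since last visit"))
  s3 <- if (stats::runif(1) < 0.3) {
    paste("compared with prior study on",
          format(visit_date - sample.int(400L, 1L), "%Y-%m-%d"))
  } else {
    paste(pick(.benign_fillers, 5L), collapse = " ")
  }
  paste(s1, s2, s3, sep = ". ")
}

#' Generate a synthetic cohort of visit notes and outcomes
#'
#' Visit timelines are generated first; deaths are then assigned — patients
#' drawn in seeded random order, death 1-45 days after the last visit —
#' until the realized survival-negative label share reaches
#' `1 - positive_fraction_target`, so the label prevalence matches the
#' target by construction. Surviving patients either have follow-up well
#' beyond the horizon, or (a `censor_fraction` subset) follow-up inside it,
#' which censors their tail visits. Notes of dying patients dated within 90
#' days of death carry a fatal-signal phrase with probability
#' `signal_strength`. Output is byte-identical across runs for a given
#' config (seed included).
#'
#' @param config a [cohort_config()].
#' @return list with `notes` (data frame: patient_id, note_id, visit_date,
#'   note_type, text) and `outcomes` (data frame: patient_id, death_date,
#'   last_followup_date).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_patients
  horizon <- 91L
  n_visits <- if (config$visits_law == "geometric") {
    pmin(config$max_visits,
         2L + stats::rgeom(n, prob = 1 / (config$visits_mean - 1)))
  } else {
    pmin(config$max_visits,
         pmax(2L, as.integer(round(stats::rlnorm(
           n, config$visits_meanlog, config$visits_sdlog)))))
  }
  start <- as.Date("2012-01-01") + sample.int(1461L, n, replace = TRUE) - 1L

  dates <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_visits[i]
    same <- stats::runif(k - 1L) < config$same_day_prob
    gaps <- ifelse(same, 0L,
                   pmax(1L, as.integer(round(stats::rlnorm(
                     k - 1L, config$gap_meanlog, config$gap_sdlog)))))
    dates[[i]] <- start[i] + cumsum(c(0L, gaps))
  }

  # provisional outcome state: everyone alive
  censored <- stats::runif(n) < config$censor_fraction
  delta_death <- sample.int(45L, n, replace = TRUE)           # if they die
  fu_long <- 92L + sample.int(301L, n, replace = TRUE) - 1L   # if alive
  fu_short <- sample.int(92L, n, replace = TRUE) - 1L         # if censored

  neg_if_dead <- vapply(seq_len(n), function(i) {
    death <- dates[[i]][n_visits[i]] + delta_death[i]
    sum(as.integer(death - dates[[i]]) <= horizon)
  }, integer(1))
  undef_if_cens <- vapply(seq_len(n), function(i) {
    fu <- dates[[i]][n_visits[i]] + fu_short[i]
    sum(as.integer(fu - dates[[i]]) <= horizon)
  }, integer(1))

  labeled_alive <- ifelse(censored, n_visits - undef_if_cens, n_visits)
  dead <- logical(n)
  labeled_total <- sum(labeled_alive)
  neg_total <- 0L
  for (i in sample.int(n)) {
    if (labeled_total > 0L &&
        neg_total / labeled_total >= 1 - config$positive_fraction_target) break
    labeled_total <- labeled_total - labeled_alive[i] + n_visits[i]
    neg_total <- neg_total + neg_if_dead[i]
    dead[i] <- TRUE
  }

  death_date <- as.Date(rep(NA, n))
  last_fu <- as.Date(rep(NA, n))
  for (i in seq_len(n)) {
    last <- dates[[i]][n_visits[i]]
    if (dead[i]) {
      death_date[i] <- last + delta_death[i]
      last_fu[i] <- death_date[i]
    } else if (censored[i]) {
      last_fu[i] <- last + fu_short[i]
    } else {
      last_fu[i] <- last + fu_long[i]
    }
  }

  patient_id <- sprintf("P%05d", seq_len(n))
  total_notes <- sum(n_visits)
  pid <- rep(patient_id, n_visits)
  vdate <- as.Date(unlist(lapply(dates, as.integer)), origin = "1970-01-01")
  ntype <- sample(config$note_types, total_notes, replace = TRUE)
  note_id <- sprintf("N%07d", seq_len(total_notes))

  text <- character(total_notes)
  row <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n_visits[i])) {
      row <- row + 1L
      tx <- compose_benign_note(dates[[i]][j])
      if (dead[i] &&
          as.integer(death_date[i] - dates[[i]][j]) <= 90L &&
          stats::runif(1) < config$signal_strength) {
        tx <- paste0(tx, ". ", sample(.fatal_phrases, 1L))
      }
      text[row] <- tx
    }
  }

  notes <- data.frame(patient_id = pid, note_id = note_id, visit_date = vdate,
                      note_type = ntype, text = text, stringsAsFactors = FALSE)
  outcomes <- data.frame(patient_id = patient_id, death_date = death_date,
                         last_followup_date = last_fu, stringsAsFactors = FALSE)
  list(notes = notes, outcomes = outcomes)
}

#' Summary statistics of a cohort
#'
#' Exact counts: patients, visits, per-class visit labels (survival-positive
#' / survival-negative / censored-undefined at the 91-day horizon), and the
#' visits-per-patient histogram (which sums to the number of patients).
#'
#' @param notes notes data frame.
#' @param outcomes outcomes data frame.
#' @param horizon_days labelling horizon; default 91.
#' @return list of class `cohort_stats`.
#' @export
cohort_stats <- function(notes, outcomes, horizon_days = 91L) {
  if (is.null(notes) || nrow(notes) == 0L) stop("empty corpus: no notes")
  oc <- outcomes[match(notes$patient_id, outcomes$patient_id), ]
  lab <- label_visit(notes$visit_date, oc$death_date, oc$last_followup_date,
                     horizon_days)
  hist <- table(table(notes$patient_id))
  structure(list(n_patients = length(unique(notes$patient_id)),
                 n_visits = nrow(notes),
                 label_counts = c(POS = sum(lab == "POS"),
                                  NEG = sum(lab == "NEG"),
                                  UNDEFINED = sum(lab == "UNDEFINED")),
                 visits_per_patient = hist),
            class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat("cohort:", x$n_patients, "patients,", x$n_visits, "visits\n")
  cat("labels: POS", x$label_counts["POS"], "| NEG", x$label_counts["NEG"],
      "| UNDEFINED", x$label_counts["UNDEFINED"], "\n")
  invisible(x)
}
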