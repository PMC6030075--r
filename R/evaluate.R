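#' ROC AUC with bootstrap confidence interval and best cut-off
#'
#' AUC by the rank (Mann-Whitney) method with tied scores contributing 1/2.
#' The confidence interval is a percentile bootstrap; when `patient` is
#' given, whole patients are resampled (cluster bootstrap) because visits
#' within a patient are dependent. The best cut-off maximizes sensitivity +
#' specificity (Youden's J) over the observed scores, ties resolved to the
#' lower threshold; a score is called positive when it is >= the cut-off.
#'
#' @param scores numeric vector of predicted survival probabilities (padded
#'   and censored visits must already be excluded).
#' @param labels logical or "POS"/"NEG" vector; TRUE/"POS" is the positive
#'   class.
#' @param n_boot bootstrap replicates (0 = no interval).
#' @param seed seed for the bootstrap.
#' @param patient optional patient id per visit for cluster bootstrap.
#' @param conf confidence level; default 0.95.
#' @return list: `auc`, `ci_low`, `ci_high`, `best_cutoff`.
#' @export
roc_auc <- function(scores, labels, n_boot = 0L, seed = 1L, patient = NULL,
                    conf = 0.95) {
  pos <- as_pos(labels)
  if (length(scores) != length(pos)) stop("scores and labels differ in length")
  if (all(pos) || all(!pos))
    stop("degenerate input: both classes must be present for ROC analysis")
  auc <- auc_rank(scores, pos)

  # best cutoff by Youden's J; candidates are the observed scores
  cand <- sort(unique(scores))
  n_pos <- sum(pos); n_neg <- sum(!pos)
  sens <- vapply(cand, function(c) sum(scores >= c & pos) / n_pos, numeric(1))
  spec <- vapply(cand, function(c) sum(scores < c & !pos) / n_neg, numeric(1))
  j <- sens + spec
  best_cutoff <- cand[which.max(j)]  # which.max takes the first (lowest) tie

  ci_low <- NA_real_; ci_high <- NA_real_
  if (n_boot > 0L) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
    boots <- numeric(n_boot)
    if (is.null(patient)) {
      nn <- length(scores)
      for (b in seq_len(n_boot)) {
        ix <- sample.int(nn, replace = TRUE)
        boots[b] <- auc_rank_safe(scores[ix], pos[ix])
      }
    } else {
      groups <- split(seq_along(scores), patient)
      np <- length(groups)
      for (b in seq_len(n_boot)) {
        ix <- unlist(groups[sample.int(np, replace = TRUE)], use.names = FALSE)
        boots[b] <- auc_rank_safe(scores[ix], pos[ix])
      }
    }
    boots <- boots[!is.na(boots)]
    alpha <- (1 - conf) / 2
    qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
    ci_low <- qs[1]; ci_high <- qs[2]
  }
  list(auc = auc, ci_low = ci_low, ci_high = ci_high,
       best_cutoff = best_cutoff)
}

as_pos <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  labels == "POS"
}

auc_rank <- function(scores, pos) {
  r <- rank(scores)  # midranks handle ties (each tied pair counts 1/2)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

auc_rank_safe <- function(scores, pos) {
  if (all(pos) || all(!pos)) return(NA_real_)
  auc_rank(scores, pos)
}

#' Brier score
#'
#' Mean squared difference between the predicted survival probability and
#' the binary outcome (1 = survival-positive).
#'
#' @param scores probabilities in \[0,1\].
#' @param labels logical or "POS"/"NEG".
#' @return scalar in \[0,1\].
#' @export
brier <- function(scores, labels) {
  if (length(scores) == 0L) stop("empty input: Brier score undefined")
  if (any(scores < 0 | scores > 1)) stop("scores must be probabilities in [0,1]")
  pos <- as_pos(labels)
  mean((scores - as.numeric(pos))^2)
}

#' Decile calibration table
#'
#' Bins predictions into ten half-open probability bins \[0,0.1), \[0.1,0.2),
#' ..., \[0.9,1.0\] and reports, per bin, the number of visits, the mean
#' predicted survival probability (%) and the observed survival rate (%).
#' Empty bins are kept with n = 0. Bin counts always sum to the number of
#' evaluated visits.
#'
#' @param scores probabilities in \[0,1\].
#' @param labels logical or "POS"/"NEG".
#' @return data frame: bin, lo, hi, n, mean_predicted_pct, observed_pct.
#' @export
calibration_deciles <- function(scores, labels) {
  if (length(scores) == 0L) stop("empty input: no predictions to bin")
  pos <- as_pos(labels)
  bin <- pmin(floor(scores * 10) + 1L, 10L)
  out <- data.frame(bin = 1:10,
                    lo = seq(0, 0.9, 0.1), hi = seq(0.1, 1.0, 0.1),
                    n = 0L, mean_predicted_pct = NA_real_,
                    observed_pct = NA_real_)
  tab <- table(factor(bin, levels = 1:10))
  out$n <- as.integer(tab)
  for (b in 1:10) {
    if (out$n[b] > 0L) {
      sel <- bin == b
      out$mean_predicted_pct[b] <- 100 * mean(scores[sel])
      out$observed_pct[b] <- 100 * mean(pos[sel])
    }
  }
  out
}

#' Per-stratum AUC
#'
#' AUC computed separately within each stratum (e.g. primary cancer site).
#' Strata where one class is missing are reported with `auc = NA` and
#' flagged, never dropped silently.
#'
#' @param scores,labels as in [roc_auc()].
#' @param strata character vector, one stratum label per visit.
#' @return data frame: stratum, n, auc, defined.
#' @export
stratified_auc <- function(scores, labels, strata) {
  pos <- as_pos(labels)
  out <- lapply(split(seq_along(scores), strata), function(ix) {
    a <- auc_rank_safe(scores[ix], pos[ix])
    data.frame(n = length(ix), auc = a, defined = !is.na(a))
  })
  df <- do.call(rbind, out)
  df <- cbind(data.frame(stratum = names(out), stringsAsFactors = FALSE), df)
  rownames(df) <- NULL
  df
}

#' Full evaluation report for a prediction table
#'
#' Computes ROC AUC with patient-level bootstrap CI and best cut-off, Brier
#' score, precision-recall AUC, and the decile calibration table, over
#' non-padded, non-censored visits (rows labelled POS or NEG).
#'
#' @param pred predictions data frame (see [predict_sequences()]); rows with
#'   `true_label` UNDEFINED are excluded.
#' @param n_boot bootstrap replicates for the AUC interval.
#' @param seed bootstrap seed.
#' @param strata optional data frame (patient_id, stratum) for per-stratum
#'   AUC.
#' @return list of class `evaluation_report`.
#' @export
evaluate_predictions <- function(pred, n_boot = 200L, seed = 1L,
                                 strata = NULL) {
  if (inherits(pred, "prediction_set")) pred <- pred$predictions
  keep <- pred$true_label %in% c("POS", "NEG")
  pred <- pred[keep, , drop = FALSE]
  if (nrow(pred) == 0L) stop("empty input: no evaluable visits")
  roc <- roc_auc(pred$p_survival, pred$true_label, n_boot = n_boot,
                 seed = seed, patient = pred$patient_id)
  rep <- list(auc = roc$auc, ci_low = roc$ci_low, ci_high = roc$ci_high,
              best_cutoff = roc$best_cutoff,
              brier = brier(pred$p_survival, pred$true_label),
              pr_auc = pr_auc(pred$p_survival, pred$true_label),
              calibration = calibration_deciles(pred$p_survival,
                                                pred$true_label),
              n_visits = nrow(pred),
              n_patients = length(unique(pred$patient_id)))
  if (!is.null(strata)) {
    s <- strata$stratum[match(pred$patient_id, strata$patient_id)]
    rep$per_stratum_auc <- stratified_auc(pred$p_survival, pred$true_label, s)
  }
  structure(rep, class = "evaluation_report")
}

#' Precision-recall AUC
#'
#' Area under the precision-recall curve by step-wise interpolation over
#' descending score thresholds (average precision).
#'
#' @param scores,labels as in [roc_auc()].
#' @return scalar in \[0,1\].
#' @export
pr_auc <- function(scores, labels) {
  pos <- as_pos(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- pos[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  # average precision: mean of precision at each positive hit
  sum(precision[y]) / sum(y)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("AUC %.3f [%.3f-%.3f], best cutoff %.3f\n", x$auc,
              x$ci_low, x$ci_high, x$best_cutoff))
  cat(sprintf("Brier %.4f | PR-AUC %.3f | %d visits / %d patients\n",
              x$brier, x$pr_auc, x$n_visits, x$n_patients))
  invisible(x)
}

#' Write an evaluation report to a directory
#'
#' `report.json` holds the scalar metrics, `calibration.csv` the decile
#' table, and `roc.csv` / `pr.csv` the curve point lists.
#'
#' @param report an `evaluation_report`.
#' @param pred the predictions data frame it was computed from.
#' @param dir output directory.
#' @export
write_evaluation <- function(report, pred, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scal <- report[c("auc", "ci_low", "ci_high", "best_cutoff", "brier",
                   "pr_auc", "n_visits", "n_patients")]
  writeLines(jsonlite::toJSON(scal, auto_unbox = TRUE, digits = NA),
             file.path(dir, "report.json"))
  utils::write.csv(report$calibration, file.path(dir, "calibration.csv"),
                   row.names = FALSE)
  if (inherits(pred, "prediction_set")) pred <- pred$predictions
  keep <- pred$true_label %in% c("POS", "NEG")
  s <- pred$p_survival[keep]; p <- pred$true_label[keep] == "POS"
  cand <- sort(unique(s))
  roc_df <- data.frame(
    threshold = cand,
    sensitivity = vapply(cand, function(c) sum(s >= c & p) / sum(p), numeric(1)),
    specificity = vapply(cand, function(c) sum(s < c & !p) / sum(!p), numeric(1)))
  utils::write.csv(roc_df, file.path(dir, "roc.csv"), row.names = FALSE)
  ord <- order(s, decreasing = TRUE)
  y <- p[ord]
  pr_df <- data.frame(recall = cumsum(y) / sum(y),
                      precision = cumsum(y) / seq_along(y))
  utils::write.csv(pr_df, file.path(dir, "pr.csv"), row.names = FALSE)
  if (!is.null(report$per_stratum_auc))
    utils::write.csv(report$per_stratum_auc,
                     file.path(dir, "stratum_auc.csv"), row.names = FALSE)
  invisible(dir)
}
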