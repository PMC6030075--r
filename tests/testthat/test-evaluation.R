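test_that("AUC matches exhaustive pair counting and reference implementations", {
  set.seed(14)
  scores <- round(runif(30), 2)  # rounding forces some ties
  labels <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.7, 0.3))
  got <- roc_auc(scores, labels)$auc
  expect_equal(got, oracle_pair_auc(scores, labels), tolerance = 1e-12)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("a constant predictor scores exactly one half", {
  labels <- c(rep("POS", 13), rep("NEG", 7))
  expect_identical(roc_auc(rep(0.8, 20), labels)$auc, 0.5)
  # and perfect separation scores one
  expect_equal(roc_auc(as.numeric(labels == "POS"), labels)$auc, 1.0)
  expect_error(roc_auc(runif(5), rep("POS", 5)), "degenerate")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(2)
  s <- runif(40); l <- sample(c("POS", "NEG"), 40, replace = TRUE)
  a <- roc_auc(s, l)$auc
  expect_equal(roc_auc(qlogis(s * 0.98 + 0.01), l)$auc, a)
  expect_equal(roc_auc(s^3, l)$auc, a)
})

test_that("the best cut-off maximizes sensitivity plus specificity", {
  scores <- c(0.1, 0.2, 0.6, 0.7, 0.8, 0.9)
  labels <- c("NEG", "NEG", "NEG", "POS", "POS", "POS")
  out <- roc_auc(scores, labels)
  expect_equal(out$best_cutoff, 0.7)
  # ties resolve to the lower threshold
  out2 <- roc_auc(c(0.2, 0.8), c("NEG", "POS"))
  expect_equal(out2$best_cutoff, 0.8)
})

test_that("patient-level bootstrap intervals bracket the point estimate", {
  set.seed(9)
  n <- 200
  pid <- rep(sprintf("P%02d", 1:20), each = 10)
  lab <- sample(c("POS", "NEG"), n, replace = TRUE, prob = c(0.8, 0.2))
  sc <- ifelse(lab == "POS", rnorm(n, 0.7, 0.2), rnorm(n, 0.4, 0.2))
  sc <- pmin(pmax(sc, 0), 1)
  out <- roc_auc(sc, lab, n_boot = 200, seed = 3, patient = pid)
  expect_lt(out$ci_low, out$auc)
  expect_gt(out$ci_high, out$auc)
  out2 <- roc_auc(sc, lab, n_boot = 200, seed = 3, patient = pid)
  expect_identical(out, out2)
})

test_that("Brier score equals the mean squared error in closed form", {
  labels <- c("POS", "NEG", "POS", "POS")
  expect_equal(brier(c(1, 0, 1, 1), labels), 0)
  expect_equal(brier(rep(0.5, 4), labels), 0.25)
  set.seed(4)
  s <- runif(10); l <- sample(c("POS", "NEG"), 10, replace = TRUE)
  expect_equal(brier(s, l), mean((s - (l == "POS"))^2), tolerance = 1e-15)
  # prevalence-constant predictor
  l2 <- c(rep("POS", 8), rep("NEG", 2))
  p_bar <- 0.8
  expect_equal(brier(rep(p_bar, 10), l2), p_bar * (1 - p_bar),
               tolerance = 1e-12)
  expect_error(brier(numeric(0), character(0)), "empty")
  expect_error(brier(c(1.4), "POS"), "probabilities")
})

test_that("decile bins are half-open and counts sum to the input size", {
  expect_equal(calibration_deciles(0.05, "POS")$n[1], 1L)
  tab <- calibration_deciles(c(0.05, 0.15), c("POS", "NEG"))
  expect_equal(tab$n[1:2], c(1L, 1L))
  # 1.0 falls in the last bin
  tab2 <- calibration_deciles(c(0.95, 1.0), c("POS", "POS"))
  expect_equal(tab2$n[10], 2L)
  expect_equal(tab2$observed_pct[10], 100)

  set.seed(6)
  s <- runif(500); l <- sample(c("POS", "NEG"), 500, replace = TRUE)
  tab3 <- calibration_deciles(s, l)
  expect_equal(sum(tab3$n), 500L)
  # brute-force recount per bin
  for (b in 1:10) {
    lo <- (b - 1) / 10; hi <- b / 10
    sel <- if (b < 10) s >= lo & s < hi else s >= lo & s <= hi
    expect_equal(tab3$n[b], sum(sel))
    if (sum(sel) > 0) {
      expect_equal(tab3$mean_predicted_pct[b], 100 * mean(s[sel]))
      expect_equal(tab3$observed_pct[b], 100 * mean(l[sel] == "POS"))
    }
  }
})

test_that("per-stratum AUC is consistent and flags undefined strata", {
  set.seed(7)
  s <- runif(60); l <- sample(c("POS", "NEG"), 60, replace = TRUE)
  whole <- stratified_auc(s, l, rep("all", 60))
  expect_equal(whole$auc, roc_auc(s, l)$auc)
  # two strata with identical multisets give equal AUCs
  two <- stratified_auc(c(s, s), c(l, l), rep(c("a", "b"), each = 60))
  expect_equal(two$auc[1], two$auc[2])
  # three strata, each checked against the pair-counting oracle
  strata <- sample(c("x", "y", "z"), 60, replace = TRUE)
  tab <- stratified_auc(s, l, strata)
  for (st in c("x", "y", "z")) {
    ix <- strata == st
    expect_equal(tab$auc[tab$stratum == st],
                 oracle_pair_auc(s[ix], l[ix] == "POS"), tolerance = 1e-12)
  }
  # a stratum lacking one class is reported undefined, not dropped
  one <- stratified_auc(c(0.3, 0.5, 0.2), c("POS", "POS", "NEG"),
                        c("u", "u", "v"))
  expect_true(all(c("u", "v") %in% one$stratum))
  expect_false(one$defined[one$stratum == "v"])
})

test_that("evaluation reports exclude censored visits and serialize cleanly", {
  fit <- small_trained_pipeline()
  rep <- evaluate_predictions(fit$predictions, n_boot = 50, seed = 2)
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  expect_equal(sum(rep$calibration$n), rep$n_visits)
  df <- fit$predictions$predictions
  expect_equal(rep$n_visits, sum(df$true_label %in% c("POS", "NEG")))
  dir <- tempfile()
  write_evaluation(rep, fit$predictions, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  back <- jsonlite::fromJSON(file.path(dir, "report.json"))
  expect_equal(back$auc, rep$auc, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "calibration.csv")))
  expect_true(file.exists(file.path(dir, "roc.csv")))
})
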