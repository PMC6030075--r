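tiny_config <- function(...) model_config(D = 4, H1 = 5, H2 = 3, epochs = 2,
                                          batch_size = 4, seed = 7, ...)

test_that("the architecture has the stated layers and parameter counts", {
  cfg <- model_config(D = 10, H1 = 50, H2 = 25)
  p <- build_model(cfg)
  layers <- attr(p, "layers")
  expect_equal(names(layers), c("lstm_1", "batch_normalization_1", "lstm_2",
                                "timedist_output"))
  expect_equal(unname(layers["lstm_1"]), 4 * 50 * (10 + 50 + 1))
  expect_equal(unname(layers["lstm_2"]), 4 * 25 * (50 + 25 + 1))
  expect_equal(dim(p$Wx1), c(10, 200))
  expect_equal(dim(p$Wh1), c(50, 200))
  expect_equal(length(p$b1), 200)
  expect_equal(attr(p, "n_params"), sum(layers))
  expect_error(model_config(D = 4, dropout = 1), "dropout")
  expect_error(model_config(D = 4, class_weights = c(POS = -1, NEG = 1, PAD = 1)),
               "class_weights")
})

test_that("softmax outputs are probability vectors at every timestep", {
  cfg <- tiny_config()
  p <- build_model(cfg)
  x <- array(rnorm(3 * 6 * 4), c(3, 6, 4))
  fwd <- notecast:::model_forward(p, x, cfg, training = FALSE)
  sums <- apply(fwd$probs, c(1, 2), sum)
  expect_equal(unname(sums), matrix(1, 3, 6), tolerance = 1e-12)
  expect_true(all(fwd$probs >= 0))
})

test_that("the weighted time-distributed loss matches direct evaluation", {
  # perfect one-hot predictions give zero loss
  y <- matrix(c(1L, 2L, 3L), 1, 3)
  perfect <- array(0, c(1, 3, 3))
  perfect[1, 1, 1] <- 1; perfect[1, 2, 2] <- 1; perfect[1, 3, 3] <- 1
  expect_equal(loss_weighted_ce(y, perfect), 0)

  # hand-constructed 3-timestep example evaluated with the formula directly
  probs <- array(0, c(1, 3, 3))
  probs[1, 1, ] <- c(0.7, 0.2, 0.1)
  probs[1, 2, ] <- c(0.1, 0.6, 0.3)
  probs[1, 3, ] <- c(0.25, 0.25, 0.5)
  w <- c(POS = 2, NEG = 1, PAD = 0.1)
  by_hand <- -(2 * log(0.7) + 1 * log(0.6) + 0.1 * log(0.5)) / 3
  expect_equal(loss_weighted_ce(y, probs, w), by_hand, tolerance = 1e-14)

  # linear in the weights
  expect_equal(loss_weighted_ce(y, probs, w * 2), 2 * by_hand,
               tolerance = 1e-14)

  # censored timesteps contribute zero
  y2 <- matrix(c(1L, 4L, 3L), 1, 3)
  by_hand2 <- -(2 * log(0.7) + 0.1 * log(0.5)) / 3
  expect_equal(loss_weighted_ce(y2, probs, w), by_hand2, tolerance = 1e-14)

  # malformed probabilities are rejected
  bad <- probs; bad[1, 1, ] <- c(0.5, 0.2, 0.1)
  expect_error(loss_weighted_ce(y, bad, w), "sum to 1")
})

test_that("analytic gradients agree with finite differences", {
  cfg <- model_config(D = 3, H1 = 4, H2 = 3, dropout = 0, seed = 11)
  params <- build_model(cfg)
  bn_state <- attr(params, "bn_state")
  set.seed(3)
  x <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  y <- matrix(c(1L, 2L, 3L, 2L, 1L, 4L), 2, 3)
  fwd <- notecast:::model_forward(params, x, cfg, training = TRUE,
                                  bn_state = bn_state)
  grads <- notecast:::model_backward(params, x, y, fwd, cfg)
  loss_at <- function(p) {
    f <- notecast:::model_forward(p, x, cfg, training = TRUE,
                                  bn_state = bn_state)
    loss_weighted_ce(y, f$probs, cfg$class_weights)
  }
  eps <- 1e-6
  for (nm in names(grads)) {
    idx <- seq_len(min(4, length(grads[[nm]])))
    for (i in idx) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                   info = paste("param", nm, "index", i))
    }
  }
})

test_that("the learning rate follows the per-epoch decay schedule", {
  cfg <- model_config(D = 4, lr = 0.001, lr_decay = 1e-4)
  expect_equal(lr_at_epoch(cfg, 0), 0.001)
  expect_equal(lr_at_epoch(cfg, 10), 0.001 / (1 + 1e-4 * 10))
})

test_that("training learns the planted signal beyond the majority baseline", {
  fit <- small_trained_pipeline()
  hist <- fit$model$history
  # loss decreases over training
  expect_lt(hist$loss[nrow(hist)], hist$loss[1])
  # accuracy on real timesteps beats always-predicting the majority class
  ds <- fit$splits$train
  real <- ds$y[ds$y <= 2L]
  majority <- max(table(real)) / length(real)
  expect_gt(hist$train_acc_real[nrow(hist)], majority)
  expect_error(train_model(subset_dataset(ds, integer(0)), NULL,
                           fit$model$config), "empty")
})

test_that("predictions are causal: future inputs cannot change past outputs", {
  fit <- small_trained_pipeline()
  model <- fit$model
  ds <- fit$splits$test
  x <- ds$x[1, , , drop = FALSE]
  base <- notecast:::model_forward(model$params, x, model$config,
                                   training = FALSE)$probs
  set.seed(99)
  for (r in 1:5) {
    t_mod <- sample(2:ds$max_len, 1)
    x2 <- x
    x2[1, t_mod:ds$max_len, ] <- rnorm(length(x2[1, t_mod:ds$max_len, ]))
    pert <- notecast:::model_forward(model$params, x2, model$config,
                                     training = FALSE)$probs
    expect_identical(pert[1, seq_len(t_mod - 1), ],
                     base[1, seq_len(t_mod - 1), ])
  }
})

test_that("appending extra zero padding never changes real-timestep output", {
  fit <- small_trained_pipeline()
  model <- fit$model
  ds <- fit$splits$test
  x <- ds$x[2, , , drop = FALSE]
  xlong <- array(0, c(1, ds$max_len + 7, ds$D))
  xlong[1, seq_len(ds$max_len), ] <- x[1, , ]
  a <- notecast:::model_forward(model$params, x, model$config,
                                training = FALSE)$probs
  b <- notecast:::model_forward(model$params, xlong, model$config,
                                training = FALSE)$probs
  expect_identical(a[1, , ], b[1, seq_len(ds$max_len), ])
})

test_that("raising the survival-class weight lowers the false-negative rate", {
  fit <- small_trained_pipeline()
  tr <- fit$splits$train; va <- fit$splits$validation
  fn_rate <- function(pos_weight) {
    cfg <- model_config(D = tr$D, H1 = 8, H2 = 4, epochs = 6, seed = 21,
                        class_weights = c(POS = pos_weight, NEG = 1,
                                          PAD = 0.1))
    m <- train_model(tr, NULL, cfg)
    pred <- predict_sequences(m, va)
    df <- pred$predictions
    df <- df[df$true_label %in% c("POS", "NEG"), ]
    # false negative: a true survivor predicted below 0.5
    mean(df$p_survival[df$true_label == "POS"] < 0.5)
  }
  expect_lte(fn_rate(8), fn_rate(0.25))
})

test_that("prediction tables align with the manifest and round-trip as TSV", {
  fit <- small_trained_pipeline()
  pred <- fit$predictions
  df <- pred$predictions
  expect_true(all(df$p_survival >= 0 & df$p_survival <= 1))
  one <- df[df$patient_id == df$patient_id[1], ]
  expect_equal(one$visit_index, seq_len(nrow(one)))
  path <- tempfile(fileext = ".tsv")
  write_predictions(pred, path)
  back <- read_predictions(path)
  expect_equal(back$p_survival, df$p_survival, tolerance = 1e-15)
  expect_equal(back$note_id, df$note_id)
})

test_that("a saved model reloads and reproduces its predictions exactly", {
  fit <- small_trained_pipeline()
  path <- tempfile(fileext = ".json")
  write_model(fit$model, path)
  back <- read_model(path)
  p1 <- predict_sequences(fit$model, fit$splits$test)$predictions
  p2 <- predict_sequences(back, fit$splits$test)$predictions
  expect_equal(p1$p_survival, p2$p_survival, tolerance = 1e-12)
})
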