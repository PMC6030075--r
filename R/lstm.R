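#' Model configuration for the recurrent survival classifier
#'
#' Architecture: input (D) -> LSTM (H1 units, unidirectional, sequence
#' output) -> frame-wise batch normalization -> LSTM (H2) -> dropout ->
#' per-timestep dense + softmax over 3 classes (survival-positive,
#' survival-negative, padded). Trained with Adam on the time-distributed
#' weighted cross-entropy, class weights 2x / 1x / 0.1x, with the learning
#' rate decayed per epoch.
#'
#' @param D input (note-vector) dimension.
#' @param H1,H2 hidden sizes of the stacked LSTM layers; defaults 50 and 25.
#' @param dropout dropout rate between the second LSTM and the output layer;
#'   default 0.10.
#' @param lr initial Adam learning rate; default 0.001.
#' @param lr_decay per-epoch decay; the rate at 0-based epoch k is
#'   `lr / (1 + lr_decay * k)`. Default 0.0001.
#' @param epochs training epochs; default 30.
#' @param batch_size patients per batch; default 32.
#' @param class_weights named positive weights for the true class of each
#'   timestep: POS, NEG, PAD. Censored (UNDEFINED) timesteps always get
#'   weight 0. Default c(POS = 2, NEG = 1, PAD = 0.1).
#' @param clip_norm global gradient-norm clip; default 5.
#' @param bn_momentum,bn_eps batch-normalization running-average momentum
#'   and variance floor.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout masks.
#' @return list of class `model_config`.
#' @export
model_config <- function(D, H1 = 50L, H2 = 25L, dropout = 0.10,
                         lr = 0.001, lr_decay = 1e-4, epochs = 30L,
                         batch_size = 32L,
                         class_weights = c(POS = 2, NEG = 1, PAD = 0.1),
                         clip_norm = 5, bn_momentum = 0.99, bn_eps = 1e-3,
                         seed = 1L) {
  stopifnot(D >= 1L, H1 >= 1L, H2 >= 1L)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (!all(c("POS", "NEG", "PAD") %in% names(class_weights)) ||
      any(class_weights <= 0))
    stop("class_weights must be positive and named POS, NEG, PAD")
  structure(list(D = as.integer(D), H1 = as.integer(H1), H2 = as.integer(H2),
                 dropout = dropout, n_classes = 3L, lr = lr,
                 lr_decay = lr_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 class_weights = class_weights, clip_norm = clip_norm,
                 bn_momentum = bn_momentum, bn_eps = bn_eps,
                 seed = as.integer(seed)),
            class = "model_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize model parameters
#'
#' Seeded Glorot-uniform weights; LSTM forget-gate biases start at 1.
#' Reports the layer structure and trainable parameter count as attributes.
#'
#' @param config a [model_config()].
#' @return named list of parameter arrays (class `model_params`) with
#'   attributes `layers` and `n_params`; LSTM layer parameter counts follow
#'   4H(D + H + 1).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  D <- config$D; H1 <- config$H1; H2 <- config$H2; C <- config$n_classes
  b1 <- numeric(4 * H1); b1[(H1 + 1):(2 * H1)] <- 1  # forget gate bias
  b2 <- numeric(4 * H2); b2[(H2 + 1):(2 * H2)] <- 1
  p <- list(
    Wx1 = glorot(D, 4 * H1), Wh1 = glorot(H1, 4 * H1), b1 = b1,
    gamma = rep(1, H1), beta = numeric(H1),
    Wx2 = glorot(H1, 4 * H2), Wh2 = glorot(H2, 4 * H2), b2 = b2,
    Wo = glorot(H2, C), bo = numeric(C)
  )
  bn_state <- list(mean = numeric(H1), var = rep(1, H1))
  n_lstm1 <- 4 * H1 * (D + H1 + 1)
  n_lstm2 <- 4 * H2 * (H1 + H2 + 1)
  n_bn <- 2 * H1
  n_out <- H2 * C + C
  structure(p, class = "model_params", bn_state = bn_state,
            layers = c(lstm_1 = n_lstm1, batch_normalization_1 = n_bn,
                       lstm_2 = n_lstm2, timedist_output = n_out),
            n_params = n_lstm1 + n_lstm2 + n_bn + n_out)
}

# ---- forward pieces -------------------------------------------------------

sigm <- function(x) 1 / (1 + exp(-x))

# x: (B,T,Din); returns h (B,T,H) plus caches for backprop
lstm_forward <- function(x, Wx, Wh, b) {
  B <- dim(x)[1]; T <- dim(x)[2]; Din <- dim(x)[3]; H <- nrow(Wh)
  h <- array(0, c(B, T, H))
  gi <- array(0, c(B, T, H)); gf <- array(0, c(B, T, H))
  gg <- array(0, c(B, T, H)); go <- array(0, c(B, T, H))
  cs <- array(0, c(B, T, H)); tc <- array(0, c(B, T, H))
  h_prev <- matrix(0, B, H); c_prev <- matrix(0, B, H)
  bmat <- matrix(b, B, 4 * H, byrow = TRUE)
  ii <- seq_len(H); ff <- H + ii; ggx <- 2 * H + ii; oo <- 3 * H + ii
  for (t in seq_len(T)) {
    xt <- matrix(x[, t, ], B, Din)
    a <- xt %*% Wx + h_prev %*% Wh + bmat
    i_t <- sigm(a[, ii, drop = FALSE])
    f_t <- sigm(a[, ff, drop = FALSE])
    g_t <- tanh(a[, ggx, drop = FALSE])
    o_t <- sigm(a[, oo, drop = FALSE])
    c_t <- f_t * c_prev + i_t * g_t
    tc_t <- tanh(c_t)
    h_t <- o_t * tc_t
    gi[, t, ] <- i_t; gf[, t, ] <- f_t; gg[, t, ] <- g_t; go[, t, ] <- o_t
    cs[, t, ] <- c_t; tc[, t, ] <- tc_t; h[, t, ] <- h_t
    h_prev <- h_t; c_prev <- c_t
  }
  list(h = h, gi = gi, gf = gf, gg = gg, go = go, cs = cs, tc = tc)
}

# dh_out: gradient wrt layer output h at every timestep
lstm_backward <- function(dh_out, cache, x, Wx, Wh) {
  B <- dim(x)[1]; T <- dim(x)[2]; Din <- dim(x)[3]; H <- nrow(Wh)
  dWx <- matrix(0, Din, 4 * H); dWh <- matrix(0, H, 4 * H); db <- numeric(4 * H)
  dx <- array(0, c(B, T, Din))
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  ii <- seq_len(H); ff <- H + ii; ggx <- 2 * H + ii; oo <- 3 * H + ii
  for (t in rev(seq_len(T))) {
    i_t <- matrix(cache$gi[, t, ], B, H); f_t <- matrix(cache$gf[, t, ], B, H)
    g_t <- matrix(cache$gg[, t, ], B, H); o_t <- matrix(cache$go[, t, ], B, H)
    c_t <- matrix(cache$cs[, t, ], B, H); tc_t <- matrix(cache$tc[, t, ], B, H)
    c_prev <- if (t > 1L) matrix(cache$cs[, t - 1L, ], B, H) else matrix(0, B, H)
    h_prev <- if (t > 1L) matrix(cache$h[, t - 1L, ], B, H) else matrix(0, B, H)
    dh <- matrix(dh_out[, t, ], B, H) + dh_next
    do_ <- dh * tc_t
    dc <- dh * o_t * (1 - tc_t^2) + dc_next
    di <- dc * g_t; df <- dc * c_prev; dg <- dc * i_t
    dc_next <- dc * f_t
    da <- cbind(di * i_t * (1 - i_t),
                df * f_t * (1 - f_t),
                dg * (1 - g_t^2),
                do_ * o_t * (1 - o_t))
    xt <- matrix(x[, t, ], B, Din)
    dWx <- dWx + crossprod(xt, da)
    dWh <- dWh + crossprod(h_prev, da)
    db <- db + colSums(da)
    dx[, t, ] <- da %*% t(Wx)
    dh_next <- da %*% t(Wh)
  }
  list(dWx = dWx, dWh = dWh, db = db, dx = dx)
}

bn_forward <- function(h, gamma, beta, eps, training, state, momentum) {
  B <- dim(h)[1]; T <- dim(h)[2]; H <- dim(h)[3]
  M <- h; dim(M) <- c(B * T, H)
  if (training) {
    mu <- colMeans(M)
    xc <- sweep(M, 2, mu)
    va <- colMeans(xc^2)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * va
  } else {
    mu <- state$mean; va <- state$var
    xc <- sweep(M, 2, mu)
  }
  ivar <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, ivar, `*`)
  Y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  dim(Y) <- c(B, T, H)
  list(y = Y, xhat = xhat, ivar = ivar, state = state)
}

bn_backward <- function(dy, cache, gamma) {
  B <- dim(dy)[1]; T <- dim(dy)[2]; H <- dim(dy)[3]
  dY <- dy; dim(dY) <- c(B * T, H)
  N <- B * T
  dxhat <- sweep(dY, 2, gamma, `*`)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dX <- sweep(dxhat, 2, s1 / N) - sweep(cache$xhat, 2, s2 / N, `*`)
  dX <- sweep(dX, 2, cache$ivar, `*`)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dim(dX) <- c(B, T, H)
  list(dx = dX, dgamma = dgamma, dbeta = dbeta)
}

softmax_rows <- function(M) {
  M <- M - apply(M, 1, max)
  E <- exp(M)
  E / rowSums(E)
}

# full forward pass; training toggles batch statistics and dropout
model_forward <- function(params, x, config, training = FALSE,
                          bn_state = NULL) {
  B <- dim(x)[1]; T <- dim(x)[2]
  if (dim(x)[3] != config$D) stop("input dimension mismatch: got ", dim(x)[3],
                                  ", model expects ", config$D)
  if (is.null(bn_state)) bn_state <- attr(params, "bn_state")
  l1 <- lstm_forward(x, params$Wx1, params$Wh1, params$b1)
  bn <- bn_forward(l1$h, params$gamma, params$beta, config$bn_eps, training,
                   bn_state, config$bn_momentum)
  l2 <- lstm_forward(bn$y, params$Wx2, params$Wh2, params$b2)
  h2 <- l2$h
  drop_mask <- NULL
  if (training && config$dropout > 0) {
    keep <- 1 - config$dropout
    drop_mask <- array((stats::runif(length(h2)) < keep) / keep, dim(h2))
    h2 <- h2 * drop_mask
  }
  H2mat <- h2; dim(H2mat) <- c(B * T, config$H2)
  logits <- sweep(H2mat %*% params$Wo, 2, params$bo, `+`)
  probs <- softmax_rows(logits)
  P <- probs; dim(P) <- c(B, T, config$n_classes)
  list(probs = P, l1 = l1, bn = bn, l2 = l2, h2 = h2, drop_mask = drop_mask,
       bn_state = bn$state)
}

#' Time-distributed weighted cross-entropy loss
#'
#' Mean over all (sequence, timestep) cells of the cross-entropy between the
#' one-hot true label and the predicted class probabilities, each multiplied
#' by the weight of the true class (POS / NEG / PAD). Censored (UNDEFINED)
#' timesteps contribute 0.
#'
#' @param y integer matrix (B x T) of label codes: 1 POS, 2 NEG, 3 PAD,
#'   4 UNDEFINED.
#' @param probs numeric array (B x T x 3) of class probabilities; every
#'   probability row must sum to 1 (tolerance 1e-6).
#' @param class_weights named weights (POS, NEG, PAD).
#' @return scalar loss.
#' @export
loss_weighted_ce <- function(y, probs,
                             class_weights = c(POS = 2, NEG = 1, PAD = 0.1)) {
  B <- dim(probs)[1]; T <- dim(probs)[2]; C <- dim(probs)[3]
  stopifnot(all(dim(y) == c(B, T)))
  rs <- apply(probs, c(1, 2), sum)
  if (any(abs(rs - 1) > 1e-6))
    stop("probability rows must sum to 1")
  w_lookup <- c(class_weights[["POS"]], class_weights[["NEG"]],
                class_weights[["PAD"]], 0)
  lam <- matrix(w_lookup[y], B, T)
  cls <- pmin(y, 3L)  # UNDEFINED has zero weight; index safely
  idx <- cbind(rep(seq_len(B), T), rep(seq_len(T), each = B),
               as.vector(cls))
  p_true <- matrix(probs[idx], B, T)
  sum(lam * (-log(pmax(p_true, 1e-300)))) / (B * T)
}

# gradient of loss wrt logits, shaped (B*T, C)
loss_grad_logits <- function(y, P, class_weights) {
  B <- dim(P)[1]; T <- dim(P)[2]; C <- dim(P)[3]
  w_lookup <- c(class_weights[["POS"]], class_weights[["NEG"]],
                class_weights[["PAD"]], 0)
  lam <- w_lookup[as.vector(y)]
  onehot <- matrix(0, B * T, C)
  cls <- pmin(as.vector(y), 3L)
  onehot[cbind(seq_len(B * T), cls)] <- 1
  Pm <- P; dim(Pm) <- c(B * T, C)
  (Pm - onehot) * lam / (B * T)
}

model_backward <- function(params, x, y, fwd, config) {
  B <- dim(x)[1]; T <- dim(x)[2]
  dlogits <- loss_grad_logits(y, fwd$probs, config$class_weights)
  H2mat <- fwd$h2; dim(H2mat) <- c(B * T, config$H2)
  dWo <- crossprod(H2mat, dlogits)
  dbo <- colSums(dlogits)
  dh2 <- dlogits %*% t(params$Wo)
  dim(dh2) <- c(B, T, config$H2)
  if (!is.null(fwd$drop_mask)) dh2 <- dh2 * fwd$drop_mask
  g2 <- lstm_backward(dh2, fwd$l2, fwd$bn$y, params$Wx2, params$Wh2)
  gb <- bn_backward(g2$dx, fwd$bn, params$gamma)
  g1 <- lstm_backward(gb$dx, fwd$l1, x, params$Wx1, params$Wh1)
  list(Wx1 = g1$dWx, Wh1 = g1$dWh, b1 = g1$db,
       gamma = gb$dgamma, beta = gb$dbeta,
       Wx2 = g2$dWx, Wh2 = g2$dWh, b2 = g2$db,
       Wo = dWo, bo = dbo)
}

clip_global_norm <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / total))
  grads
}

#' Learning rate at a given epoch
#'
#' `lr / (1 + lr_decay * epoch)` with `epoch` 0-based.
#' @param config a [model_config()].
#' @param epoch 0-based epoch index.
#' @return numeric learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  config$lr / (1 + config$lr_decay * epoch)
}

#' Train the recurrent survival classifier
#'
#' Adam on the time-distributed weighted cross-entropy with per-epoch
#' learning-rate decay, seeded patient shuffling per epoch, gradient-norm
#' clipping, and checkpointing of the best-validation-accuracy parameters.
#' Accuracy is logged both over all non-censored timesteps (padding
#' included, the over-optimistic bookkeeping) and over real visits only.
#'
#' @param train_ds,val_ds `sequence_dataset` splits; `val_ds` may be NULL.
#' @param config a [model_config()].
#' @param verbose print per-epoch progress.
#' @return object of class `survival_model`: list with `params` (best
#'   checkpoint), `final_params`, `config`, `history` (data frame: epoch,
#'   lr, loss, train_acc, train_acc_real, val_acc, val_acc_real),
#'   `best_epoch`.
#' @export
train_model <- function(train_ds, val_ds = NULL, config, verbose = FALSE) {
  stopifnot(inherits(train_ds, "sequence_dataset"),
            inherits(config, "model_config"))
  n <- length(train_ds$patient_id)
  if (n == 0L) stop("empty training split")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })

  params <- build_model(config)
  bn_state <- attr(params, "bn_state")
  pn <- names(params)
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  step <- 0L

  best_val <- -Inf; best_params <- params; best_epoch <- 0L
  hist <- vector("list", config$epochs)

  for (ep in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config, ep - 1L)
    set.seed(config$seed * 1000L + ep)
    perm <- sample.int(n)
    ep_loss <- 0; n_batch <- 0L
    for (b0 in seq(1L, n, by = config$batch_size)) {
      idx <- perm[b0:min(n, b0 + config$batch_size - 1L)]
      xb <- train_ds$x[idx, , , drop = FALSE]
      yb <- train_ds$y[idx, , drop = FALSE]
      fwd <- model_forward(params, xb, config, training = TRUE,
                           bn_state = bn_state)
      bn_state <- fwd$bn_state
      ep_loss <- ep_loss + loss_weighted_ce(yb, fwd$probs, config$class_weights)
      n_batch <- n_batch + 1L
      grads <- model_backward(params, xb, yb, fwd, config)
      grads <- clip_global_norm(grads, config$clip_norm)
      step <- step + 1L
      bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
      for (k in pn) {
        m[[k]] <- beta1 * m[[k]] + (1 - beta1) * grads[[k]]
        v[[k]] <- beta2 * v[[k]] + (1 - beta2) * grads[[k]]^2
        params[[k]] <- params[[k]] -
          lr * (m[[k]] / bc1) / (sqrt(v[[k]] / bc2) + adam_eps)
      }
    }
    attr(params, "bn_state") <- bn_state
    tr_acc <- dataset_accuracy(params, train_ds, config)
    va_acc <- if (!is.null(val_ds)) dataset_accuracy(params, val_ds, config)
              else c(all = NA_real_, real = NA_real_)
    hist[[ep]] <- data.frame(epoch = ep, lr = lr, loss = ep_loss / n_batch,
                             train_acc = tr_acc[["all"]],
                             train_acc_real = tr_acc[["real"]],
                             val_acc = va_acc[["all"]],
                             val_acc_real = va_acc[["real"]])
    score <- if (!is.null(val_ds)) va_acc[["real"]] else tr_acc[["real"]]
    if (!is.na(score) && score > best_val) {
      best_val <- score; best_params <- params; best_epoch <- ep
      attr(best_params, "bn_state") <- bn_state
    }
    if (verbose)
      message(sprintf("epoch %d: lr %.6f loss %.4f train %.3f val %.3f",
                      ep, lr, ep_loss / n_batch, tr_acc[["real"]],
                      va_acc[["real"]]))
  }
  structure(list(params = best_params, final_params = params, config = config,
                 history = do.call(rbind, hist), best_epoch = best_epoch),
            class = "survival_model")
}

dataset_accuracy <- function(params, ds, config) {
  fwd <- model_forward(params, ds$x, config, training = FALSE)
  pred <- apply(fwd$probs, c(1, 2), which.max)
  labelled <- ds$y <= 3L
  real <- ds$y <= 2L
  c(all = mean(pred[labelled] == ds$y[labelled]),
    real = if (any(real)) mean(pred[real] == ds$y[real]) else NA_real_)
}

#' @export
print.survival_model <- function(x, ...) {
  cat("survival_model: D =", x$config$D, "H =", x$config$H1, "/", x$config$H2,
      "| best epoch", x$best_epoch, "\n")
  invisible(x)
}

#' Predict per-visit survival probabilities
#'
#' Inference mode: dropout off, batch normalization using running
#' statistics, so predictions are deterministic and strictly causal (the
#' probability at visit t depends only on visits 1..t).
#'
#' @param model a trained `survival_model` (or raw `model_params` with a
#'   `config` attribute supplied via `config`).
#' @param ds a `sequence_dataset`.
#' @param use_final use the final-epoch parameters instead of the
#'   best-validation checkpoint.
#' @return list of class `prediction_set`: `probs` (n x T x 3 array) and
#'   `predictions`, a data frame with one row per real (non-padded) visit:
#'   patient_id, visit_index, visit_date, note_id, p_survival, true_label.
#' @export
predict_sequences <- function(model, ds, use_final = FALSE) {
  stopifnot(inherits(model, "survival_model"), inherits(ds, "sequence_dataset"))
  params <- if (use_final) model$final_params else model$params
  fwd <- model_forward(params, ds$x, model$config, training = FALSE)
  n <- length(ds$patient_id)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sum(ds$mask[i, ])
    man <- ds$manifest[[i]]
    rows[[i]] <- data.frame(patient_id = ds$patient_id[i],
                            visit_index = seq_len(k),
                            visit_date = man$visit_date,
                            note_id = man$note_id,
                            p_survival = fwd$probs[i, seq_len(k), 1],
                            true_label = man$label,
                            stringsAsFactors = FALSE)
  }
  structure(list(probs = fwd$probs,
                 predictions = do.call(rbind, rows)),
            class = "prediction_set")
}

#' Write / read a predictions table as TSV
#' @param pred a `prediction_set` or its `predictions` data frame.
#' @param path file path.
#' @export
write_predictions <- function(pred, path) {
  df <- if (inherits(pred, "prediction_set")) pred$predictions else pred
  df$p_survival <- sprintf("%.17g", df$p_survival)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  df$visit_date <- as.Date(df$visit_date)
  df$patient_id <- as.character(df$patient_id)
  df$note_id <- as.character(df$note_id)
  df
}

#' Save / load a trained model
#'
#' Parameters and configuration are written as a JSON file (arrays with
#' their dimensions), so checkpoints are plain text.
#'
#' @param model a `survival_model`.
#' @param path file path (.json).
#' @export
write_model <- function(model, path) {
  ser <- function(p) lapply(p, function(a) {
    if (is.matrix(a)) list(dim = dim(a), data = as.vector(a))
    else list(dim = length(a), data = as.vector(a))
  })
  bn <- attr(model$params, "bn_state")
  cfg <- unclass(model$config)
  cfg$class_weights <- as.list(cfg$class_weights)
  obj <- list(config = cfg,
              params = ser(model$params),
              bn_state = bn,
              best_epoch = model$best_epoch,
              history = model$history)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns"), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  des <- function(l) {
    out <- lapply(l, function(a) {
      d <- unlist(a$dim); x <- as.numeric(unlist(a$data))
      if (length(d) == 2L) matrix(x, d[1], d[2]) else x
    })
    out
  }
  cfg <- obj$config
  config <- model_config(D = cfg$D, H1 = cfg$H1, H2 = cfg$H2,
                         dropout = cfg$dropout, lr = cfg$lr,
                         lr_decay = cfg$lr_decay, epochs = cfg$epochs,
                         batch_size = cfg$batch_size,
                         class_weights = unlist(cfg$class_weights),
                         clip_norm = cfg$clip_norm,
                         bn_momentum = cfg$bn_momentum, bn_eps = cfg$bn_eps,
                         seed = cfg$seed)
  params <- des(obj$params)
  class(params) <- "model_params"
  attr(params, "bn_state") <- list(mean = as.numeric(unlist(obj$bn_state$mean)),
                                   var = as.numeric(unlist(obj$bn_state$var)))
  hist <- as.data.frame(lapply(obj$history, unlist), stringsAsFactors = FALSE)
  structure(list(params = params, final_params = params, config = config,
                 history = hist, best_epoch = obj$best_epoch),
            class = "survival_model")
}
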