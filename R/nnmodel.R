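# The feedforward binary rescoring classifier.  A fingerprint vector is
# mapped through fully connected ReLU layers with dropout to a 2-unit
# softmax; training minimizes cross-entropy with an L2 weight-decay
# penalty via Adam, and early stopping monitors the validation PRC-AUC
# with a fixed patience window, returning the parameters of the best
# validation epoch.

#' Configuration of the fingerprint classifier
#'
#' Defaults are the selected screening configuration: input 211, hidden
#' layers 500 and 1000, ReLU, dropout 0.1, learning rate 0.001, weight
#' decay 0.0001, early-stopping patience 15 epochs on validation PRC-AUC.
#' Batch size 64 and a 200-epoch cap are this package's defaults for
#' datasets of a few thousand rows.
#'
#' @param input_dim number of input features (212 when a docking score is
#'   appended to the fingerprint).
#' @param hidden integer vector of hidden-layer widths.
#' @param dropout dropout fraction in `[0, 1)` applied to each hidden
#'   activation during training.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty coefficient added to weight gradients.
#' @param activation hidden activation (only `"relu"` is implemented).
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param patience consecutive non-improving validation epochs tolerated
#'   before stopping.
#' @param seed integer controlling initialization, shuffling and dropout.
#' @return Object of class `tifp_net_config`.
#' @export
tifp_net_config <- function(input_dim = 211, hidden = c(500, 1000),
                            dropout = 0.1, learning_rate = 0.001,
                            weight_decay = 0.0001, activation = "relu",
                            batch_size = 64, max_epochs = 200,
                            patience = 15, seed = 1L) {
  cfg <- list(input_dim = as.integer(input_dim),
              hidden = as.integer(hidden), dropout = dropout,
              learning_rate = learning_rate, weight_decay = weight_decay,
              activation = activation, batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience), seed = as.integer(seed))
  if (cfg$input_dim < 1) stop("invalid config field: input_dim")
  if (length(cfg$hidden) < 1 || any(cfg$hidden < 1))
    stop("invalid config field: hidden")
  if (!is.finite(cfg$dropout) || cfg$dropout < 0 || cfg$dropout >= 1)
    stop("invalid config field: dropout")
  if (!is.finite(cfg$learning_rate) || cfg$learning_rate <= 0)
    stop("invalid config field: learning_rate")
  if (cfg$weight_decay < 0) stop("invalid config field: weight_decay")
  if (!identical(cfg$activation, "relu"))
    stop("invalid config field: activation (only 'relu' supported)")
  if (cfg$batch_size < 1) stop("invalid config field: batch_size")
  if (cfg$max_epochs < 1) stop("invalid config field: max_epochs")
  if (cfg$patience < 1) stop("invalid config field: patience")
  structure(cfg, class = "tifp_net_config")
}

# He-scaled Gaussian initialization, deterministic from the config seed
.nn_init <- function(config) {
  set.seed(config$seed)
  dims <- c(config$input_dim, config$hidden, 2L)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1L)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1],
                                  sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
  }
  list(W = W, b = b)
}

#' Number of trainable parameters
#'
#' @param config a [tifp_net_config()].
#' @return Total count of weights and biases.
#' @export
n_parameters <- function(config) {
  dims <- c(config$input_dim, config$hidden, 2L)
  sum(dims[-length(dims)] * dims[-1] + dims[-1])
}

.relu <- function(x) { x[x < 0] <- 0; x }

# forward pass; returns softmax probabilities and cached activations
.nn_forward <- function(params, X, dropout = 0, training = FALSE) {
  L <- length(params$W)
  A <- X; cache <- list(A0 = X); masks <- list()
  for (l in seq_len(L - 1L)) {
    Z <- A %*% params$W[[l]]
    Z <- sweep(Z, 2, params$b[[l]], "+")
    A <- .relu(Z)
    if (training && dropout > 0) {
      m <- matrix(stats::runif(length(A)) >= dropout, nrow(A), ncol(A))
      A <- A * m / (1 - dropout)
      masks[[l]] <- m
    }
    cache[[paste0("A", l)]] <- A
  }
  Z <- A %*% params$W[[L]]
  Z <- sweep(Z, 2, params$b[[L]], "+")
  Z <- Z - apply(Z, 1, max)                 # stabilized softmax
  E <- exp(Z)
  P <- E / rowSums(E)
  list(P = P, cache = cache, masks = masks)
}

# gradients of mean cross-entropy + weight decay
.nn_backward <- function(params, fwd, Y, dropout, weight_decay) {
  L <- length(params$W)
  n <- nrow(Y)
  dZ <- (fwd$P - Y) / n
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    A_prev <- fwd$cache[[paste0("A", l - 1L)]]
    gW[[l]] <- crossprod(A_prev, dZ) + weight_decay * params$W[[l]]
    gb[[l]] <- colSums(dZ)
    if (l > 1L) {
      dA <- tcrossprod(dZ, params$W[[l]])
      if (dropout > 0 && length(fwd$masks) >= l - 1L &&
          !is.null(fwd$masks[[l - 1L]]))
        dA <- dA * fwd$masks[[l - 1L]] / (1 - dropout)
      dZ <- dA * (fwd$cache[[paste0("A", l - 1L)]] > 0)
    }
  }
  list(W = gW, b = gb)
}

.adam_state <- function(params) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(params$W), vW = zero_like(params$W),
       mb = zero_like(params$b), vb = zero_like(params$b), t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (l in seq_along(params$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    params$W[[l]] <- params$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    params$b[[l]] <- params$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(params = params, state = state)
}

.check_xy <- function(x, y, input_dim, what) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop(what, " set is empty")
  if (ncol(x) != input_dim)
    stop(what, " fingerprint length ", ncol(x),
         " != config input_dim ", input_dim)
  y <- .as01(y)
  if (length(y) != nrow(x)) stop(what, " labels/rows mismatch")
  list(x = x, y = y)
}

#' Fit the fingerprint rescoring classifier
#'
#' Trains the feedforward softmax network on labelled fingerprint vectors
#' with Adam and minibatch cross-entropy, evaluating the validation
#' PRC-AUC after every epoch.  Training stops when the running best
#' validation PRC-AUC has not strictly improved for `config$patience`
#' consecutive epochs (or at `config$max_epochs`); the returned model
#' carries the parameters of the best validation epoch, not the last.
#'
#' @param x numeric matrix of training fingerprints (rows = molecules,
#'   `config$input_dim` columns).
#' @param y binary training labels (1/`"positive"` = active).
#' @param xval,yval validation fingerprints and labels; the validation
#'   set must contain both classes.
#' @param config a [tifp_net_config()].
#' @param valid_metric optional override of the early-stopping signal: a
#'   `function(epoch, probs, labels)` returning the scalar to maximize.
#'   Defaults to validation PRC-AUC.  Intended for protocol tests and
#'   calibration studies.
#' @return Object of class `tifp_net`: `config`, fitted `params`,
#'   `best_epoch`, `stopped_epoch`, `best_valid_metric` and `history`
#'   (one row per completed epoch: loss and train/validation recall,
#'   precision, ROC-AUC and PRC-AUC).
#' @seealso [predict.tifp_net()], [classify()], [grid_search()],
#'   [repeated_training()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60 * 8), 60); y <- as.integer(x[, 1] + x[, 2] > 0)
#' cfg <- tifp_net_config(input_dim = 8, hidden = c(8, 8), max_epochs = 5,
#'                        patience = 3, batch_size = 16, seed = 1)
#' fit <- tifp_net(x[1:40, ], y[1:40], x[41:60, ], y[41:60], cfg)
#' fit
#' @export
tifp_net <- function(x, y, xval, yval, config = tifp_net_config(),
                     valid_metric = NULL) {
  stopifnot(inherits(config, "tifp_net_config"))
  tr <- .check_xy(x, y, config$input_dim, "training")
  va <- .check_xy(xval, yval, config$input_dim, "validation")
  if (length(unique(va$y)) < 2)
    stop("validation set must contain both classes")
  params <- .nn_init(config)          # seeds the RNG stream
  state <- .adam_state(params)
  n <- nrow(tr$x)
  Y <- cbind(1 - tr$y, tr$y)          # one-hot: col 2 = positive
  best_metric <- -Inf; best_epoch <- 0L; best_params <- params
  wait <- 0L; history <- vector("list", config$max_epochs)
  stopped_epoch <- config$max_epochs
  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample.int(n)
    loss_sum <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      bi <- idx[start:min(start + config$batch_size - 1L, n)]
      fwd <- .nn_forward(params, tr$x[bi, , drop = FALSE],
                         config$dropout, training = TRUE)
      loss_sum <- loss_sum -
        sum(log(pmax(fwd$P[cbind(seq_along(bi), tr$y[bi] + 1L)], 1e-12)))
      grads <- .nn_backward(params, fwd, Y[bi, , drop = FALSE],
                            config$dropout, config$weight_decay)
      upd <- .adam_step(params, grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
    }
    p_tr <- .nn_forward(params, tr$x)$P[, 2]
    p_va <- .nn_forward(params, va$x)$P[, 2]
    m_tr <- .epoch_metrics(p_tr, tr$y)
    m_va <- .epoch_metrics(p_va, va$y)
    metric <- if (is.null(valid_metric)) m_va[["prc_auc"]] else
      valid_metric(epoch, p_va, va$y)
    history[[epoch]] <- data.frame(
      epoch = epoch, loss = loss_sum / n,
      train_recall = m_tr[["recall"]], train_precision = m_tr[["precision"]],
      train_roc_auc = m_tr[["roc_auc"]], train_prc_auc = m_tr[["prc_auc"]],
      valid_recall = m_va[["recall"]], valid_precision = m_va[["precision"]],
      valid_roc_auc = m_va[["roc_auc"]], valid_prc_auc = m_va[["prc_auc"]],
      valid_metric = metric)
    if (metric > best_metric) {
      best_metric <- metric; best_epoch <- epoch
      best_params <- params; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) { stopped_epoch <- epoch; break }
    }
  }
  structure(list(config = config, params = best_params,
                 best_epoch = best_epoch, stopped_epoch = stopped_epoch,
                 best_valid_metric = best_metric,
                 history = do.call(rbind, history[!vapply(history, is.null,
                                                          TRUE)])),
            class = "tifp_net")
}

# threshold-0.5 rates + ranking metrics for one epoch (NA-safe precision)
.epoch_metrics <- function(p, y) {
  cc <- confusion_counts(y, as.integer(p >= 0.5))
  bm <- suppressWarnings(basic_metrics(cc))
  both <- length(unique(y)) == 2
  c(recall = bm[["recall"]], precision = bm[["precision"]],
    roc_auc = if (both) roc_auc(p, y) else NA_real_,
    prc_auc = if (any(y == 1)) prc_auc(p, y) else NA_real_)
}

#' Predict with a fitted classifier
#'
#' Dropout is disabled at inference; the two class probabilities sum to
#' one per sample.
#'
#' @param object a fitted [tifp_net()].
#' @param newdata fingerprint matrix with `config$input_dim` columns.
#' @param type `"prob"` for positive-class probabilities, `"class"` for
#'   `"positive"`/`"negative"` at threshold 0.5, `"matrix"` for the full
#'   two-column softmax output.
#' @param ... unused.
#' @return Numeric vector, character vector or matrix, by `type`.
#' @export
predict.tifp_net <- function(object, newdata,
                             type = c("prob", "class", "matrix"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (ncol(x) != object$config$input_dim)
    stop("fingerprint length ", ncol(x), " != model input_dim ",
         object$config$input_dim)
  P <- .nn_forward(object$params, x)$P
  switch(type,
         prob = P[, 2],
         class = classify(P[, 2]),
         matrix = P)
}

#' Threshold a positive-class probability
#'
#' @param p probabilities in `[0, 1]`.
#' @param threshold decision threshold; `p >= threshold` is positive.
#' @return Character vector `"positive"`/`"negative"`.
#' @export
classify <- function(p, threshold = 0.5) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("probabilities must lie in [0, 1]")
  ifelse(p >= threshold, "positive", "negative")
}

#' @export
print.tifp_net <- function(x, ...) {
  cfg <- x$config
  cat("tifp_net:", cfg$input_dim, "->",
      paste(cfg$hidden, collapse = " -> "), "-> softmax(2)\n")
  cat("  ", format(n_parameters(cfg), big.mark = ","), "parameters;",
      "dropout", cfg$dropout, "| lr", cfg$learning_rate,
      "| weight decay", cfg$weight_decay, "\n")
  cat("  stopped at epoch", x$stopped_epoch, "| best epoch", x$best_epoch,
      sprintf("(validation PRC-AUC %.4f)", x$best_valid_metric), "\n")
  invisible(x)
}

#' @export
summary.tifp_net <- function(object, ...) {
  h <- object$history
  best <- h[h$epoch == object$best_epoch, , drop = FALSE]
  out <- list(config = object$config, best_epoch = object$best_epoch,
              stopped_epoch = object$stopped_epoch,
              n_parameters = n_parameters(object$config),
              best_row = best)
  class(out) <- "summary.tifp_net"
  out
}

#' @export
print.summary.tifp_net <- function(x, ...) {
  cat("Fingerprint classifier (", x$n_parameters, " parameters)\n", sep = "")
  cat("Trained", x$stopped_epoch, "epochs; parameters from epoch",
      x$best_epoch, "\n\nMetrics at the selected epoch:\n")
  print(round(x$best_row[, -1], 4), row.names = FALSE)
  invisible(x)
}

#' Plot the training history of a fitted classifier
#'
#' Shows train and validation PRC-AUC per epoch with the selected epoch
#' marked.
#'
#' @param x a fitted [tifp_net()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.tifp_net <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_prc_auc, h$valid_prc_auc),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "PRC-AUC", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("bottomright", c("train", "validation"),
                   lty = 1, col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Save / load a fitted classifier as JSON
#'
#' Plain-text checkpoint: config, flattened weights and training record.
#'
#' @param model a fitted `tifp_net`.
#' @param path file path.
#' @return `path` (write) or the restored model (read).
#' @export
write_tifp_net <- function(model, path) {
  obj <- list(config = unclass(model$config),
              W = lapply(model$params$W, as.vector),
              b = model$params$b,
              dims = c(model$config$input_dim, model$config$hidden, 2L),
              best_epoch = model$best_epoch,
              stopped_epoch = model$stopped_epoch,
              best_valid_metric = model$best_valid_metric,
              history = model$history)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tifp_net
#' @export
read_tifp_net <- function(path) {
  obj <- jsonlite::fromJSON(path)
  cfg <- do.call(tifp_net_config, obj$config)
  dims <- obj$dims
  W <- lapply(seq_along(obj$W), function(l)
    matrix(obj$W[[l]], dims[l], dims[l + 1]))
  structure(list(config = cfg,
                 params = list(W = W, b = lapply(obj$b, as.numeric)),
                 best_epoch = obj$best_epoch,
                 stopped_epoch = obj$stopped_epoch,
                 best_valid_metric = obj$best_valid_metric,
                 history = as.data.frame(obj$history)),
            class = "tifp_net")
}
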