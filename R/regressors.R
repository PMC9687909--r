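#' Model configuration for the velocity-correction regressors
#'
#' Defaults follow the optimized settings of the study design: a single
#' hidden layer of 10 neurons for the MLP (32 available via `hidden`),
#' batch size 32, dropout 0.02 after the first hidden layer, Adam with
#' learning rate 1e-3, 100 epochs for the MLP and 500 for the CNN and
#' LSTM.
#'
#' @param kind One of `"lasso"`, `"mlp"`, `"cnn"`, `"lstm"`.
#' @param hidden Integer vector of hidden-layer widths (mlp) or the LSTM
#'   hidden size.
#' @param penalty L1 penalty (lasso).
#' @param dropout Dropout rate after the first hidden layer (mlp).
#' @param batch_size Mini-batch size (32, 64 or 128 in the stated grid).
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param loss Training loss, `"mae"` or `"mse"`.
#' @param cnn_filters Channel counts of the three 1-D convolution layers.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#' @return Object of class `model_config`.
#' @export
model_config <- function(kind = c("mlp", "lasso", "cnn", "lstm"),
                         hidden = 10L,
                         penalty = 1e-4,
                         dropout = 0.02,
                         batch_size = 32L,
                         epochs = NULL,
                         learning_rate = 1e-3,
                         loss = c("mae", "mse"),
                         cnn_filters = c(8L, 16L, 16L),
                         seed = 1L) {
  kind <- match.arg(kind)
  loss <- match.arg(loss)
  if (is.null(epochs)) epochs <- if (kind == "mlp") 100L else 500L
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  structure(list(kind = kind, hidden = as.integer(hidden), penalty = penalty,
                 dropout = dropout, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 loss = loss, cnn_filters = as.integer(cnn_filters),
                 seed = as.integer(seed)),
            class = "model_config")
}

.train_rows <- function(table) {
  if (!is.null(table$split)) table[table$split == "train", , drop = FALSE] else table
}

.features <- function(d) as.matrix(d[, c("u_ofm", "v_ofm", "Ix", "Iy")])
.targets <- function(d) as.matrix(d[, c("u_truth", "v_truth")])

.new_model <- function(kind, fit, scaler, config, history = NULL) {
  structure(list(kind = kind, fit = fit, scaler = scaler, config = config,
                 history = history),
            class = c(paste0("af_", kind), "af_model"))
}

#' Fit the multi-output LASSO baseline
#'
#' Multivariate (4-input, 2-output) linear regression with a grouped L1
#' penalty, fitted with `glmnet` (`family = "mgaussian"`) on standardized
#' features and targets.  Coefficients shrink exactly to zero for features
#' that do not affect the targets; with a vanishing penalty the fit
#' approaches ordinary least squares.
#'
#' @param train A `sample_table` (training rows are used if a split is
#'   present).
#' @param penalty L1 penalty on the standardized scale.
#' @param config Optional [model_config()] (overrides `penalty`).
#' @return An `af_model` of kind `"lasso"`.
#' @export
fit_lasso <- function(train, penalty = 1e-4, config = NULL) {
  if (!is.null(config)) penalty <- config$penalty
  d <- .train_rows(train)
  if (!nrow(d)) stop("training table is empty", call. = FALSE)
  scaler <- feature_scaler(if (is.null(d$split)) transform(d, split = "train") else d)
  X <- scaler$scale_x(.features(d))
  Y <- scaler$scale_y(.targets(d))
  fit <- glmnet::glmnet(X, Y, family = "mgaussian", alpha = 1,
                        lambda = c(penalty * 10, penalty),
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-12)
  cfg <- if (is.null(config)) model_config("lasso", penalty = penalty) else config
  .new_model("lasso", list(glmnet = fit, lambda = penalty), scaler, cfg)
}

#' Fit the multilayer perceptron corrector
#'
#' Fully connected network `4 -> hidden (ReLU) -> 2 (linear)` with dropout
#' after the first hidden layer, trained by mini-batch Adam on
#' standardized features/targets.  Training is bit-reproducible for a
#' given `config$seed`.
#'
#' @param train A `sample_table`.
#' @param config A [model_config()] with `kind = "mlp"`.
#' @return An `af_model` of kind `"mlp"` with the training-loss history.
#' @export
fit_mlp <- function(train, config = model_config("mlp")) {
  stopifnot(config$kind == "mlp")
  d <- .train_rows(train)
  scaler <- feature_scaler(if (is.null(d$split)) transform(d, split = "train") else d)
  X <- scaler$scale_x(.features(d))
  Y <- scaler$scale_y(.targets(d))
  out <- cpp_train_mlp(X, Y, as.integer(config$hidden), config$epochs,
                       config$batch_size, config$learning_rate,
                       config$dropout, config$loss, config$seed)
  .new_model("mlp", list(W = out$W, b = out$b), scaler, config,
             history = as.numeric(out$history))
}

#' Fit the 1-D convolutional corrector
#'
#' The four features enter as a length-4 sequence with one channel; three
#' 1-D convolution layers (kernel 3, ReLU) with a max-pool after the
#' first feed a linear regression head (no softmax).
#'
#' @param train A `sample_table`.
#' @param config A [model_config()] with `kind = "cnn"`.
#' @return An `af_model` of kind `"cnn"`.
#' @export
fit_cnn <- function(train, config = model_config("cnn")) {
  stopifnot(config$kind == "cnn")
  d <- .train_rows(train)
  scaler <- feature_scaler(if (is.null(d$split)) transform(d, split = "train") else d)
  X <- scaler$scale_x(.features(d))
  Y <- scaler$scale_y(.targets(d))
  f <- config$cnn_filters
  out <- cpp_train_cnn(X, Y, f[1], f[2], f[3], config$epochs,
                       config$batch_size, config$learning_rate,
                       config$loss, config$seed)
  .new_model("cnn", out[setdiff(names(out), "history")], scaler, config,
             history = as.numeric(out$history))
}

#' Fit the LSTM corrector
#'
#' The four features are consumed as a length-4 sequence of scalars by an
#' LSTM cell (sigmoid gates, tanh candidate/state, per the standard gate
#' equations), followed by a ReLU dense layer and a linear output layer.
#'
#' @param train A `sample_table`.
#' @param config A [model_config()] with `kind = "lstm"`.
#' @return An `af_model` of kind `"lstm"`.
#' @export
fit_lstm <- function(train, config = model_config("lstm")) {
  stopifnot(config$kind == "lstm")
  d <- .train_rows(train)
  scaler <- feature_scaler(if (is.null(d$split)) transform(d, split = "train") else d)
  X <- scaler$scale_x(.features(d))
  Y <- scaler$scale_y(.targets(d))
  out <- cpp_train_lstm(X, Y, config$hidden[1], config$epochs,
                        config$batch_size, config$learning_rate,
                        config$loss, config$seed)
  .new_model("lstm", out[setdiff(names(out), "history")], scaler, config,
             history = as.numeric(out$history))
}

#' One step of the LSTM cell
#'
#' Gate equations: `i = sigma(Wi [h, x] + bi)`, `f = sigma(Wf [h, x] +
#' bf)`, `g = tanh(Wc [h, x] + bc)`, `c_t = f * c_prev + i * g`,
#' `o = sigma(Wo [h, x] + bo)`, `h_t = o * tanh(c_t)`.
#'
#' @param weights List with matrices `Wi`, `Wf`, `Wc`, `Wo` of shape
#'   `(H + d) x H` and bias rows `bi`, `bf`, `bc`, `bo`.
#' @param x_t Input at time t (n x d matrix, or vector for d = 1).
#' @param h_prev,c_prev Previous hidden and cell state (n x H).
#' @return List with `h` and `c`.
#' @export
lstm_cell_step <- function(weights, x_t, h_prev, c_prev) {
  if (is.null(dim(x_t))) x_t <- matrix(x_t, ncol = 1)
  z <- cbind(h_prev, x_t)
  sg <- function(a) 1 / (1 + exp(-a))
  off <- function(b, n) matrix(b, n, length(b), byrow = TRUE)
  n <- nrow(z)
  i <- sg(z %*% weights$Wi + off(weights$bi, n))
  f <- sg(z %*% weights$Wf + off(weights$bf, n))
  g <- tanh(z %*% weights$Wc + off(weights$bc, n))
  ct <- f * c_prev + i * g
  o <- sg(z %*% weights$Wo + off(weights$bo, n))
  list(h = o * tanh(ct), c = ct)
}

# --- forward passes (used for prediction; mirror the training code) -------

.mlp_forward <- function(fit, X) {
  A <- X
  L <- length(fit$W)
  for (l in seq_len(L)) {
    Z <- A %*% fit$W[[l]] + matrix(fit$b[[l]], nrow(A), length(fit$b[[l]]),
                                   byrow = TRUE)
    A <- if (l < L) pmax(Z, 0) else Z
  }
  A
}

.conv1d_forward <- function(A, W, b) {
  # A: array (n, L, Cin); W: array (k, Cin, Cout); pad same
  n <- dim(A)[1]; L <- dim(A)[2]; Cin <- dim(A)[3]
  k <- dim(W)[1]; Cout <- dim(W)[3]
  pad <- (k - 1) %/% 2
  out <- array(0, dim = c(n, L, Cout))
  for (co in seq_len(Cout)) {
    acc <- matrix(b[co], n, L)
    for (dk in seq_len(k)) for (ci in seq_len(Cin)) {
      w <- W[dk, ci, co]
      if (w == 0) next
      for (p in seq_len(L)) {
        q <- p + dk - 1 - pad
        if (q >= 1 && q <= L) acc[, p] <- acc[, p] + w * A[, q, ci]
      }
    }
    out[, , co] <- acc
  }
  out
}

.cnn_forward <- function(fit, X) {
  n <- nrow(X); L <- ncol(X)
  A0 <- array(X, dim = c(n, L, 1))
  relu <- function(a) { a[a < 0] <- 0; a }
  A1 <- relu(.conv1d_forward(A0, fit$W1, fit$b1))
  Lp <- L %/% 2
  P1 <- array(0, dim = c(n, Lp, dim(A1)[3]))
  for (p in seq_len(Lp))
    P1[, p, ] <- pmax(A1[, 2 * p - 1, ], A1[, 2 * p, ])
  A2 <- relu(.conv1d_forward(P1, fit$W2, fit$b2))
  A3 <- relu(.conv1d_forward(A2, fit$W3, fit$b3))
  f3 <- dim(A3)[3]
  Fm <- matrix(0, n, Lp * f3)
  for (c in seq_len(f3)) for (p in seq_len(Lp))
    Fm[, (p - 1) * f3 + c] <- A3[, p, c]
  Fm %*% fit$Wd + matrix(fit$bd, n, length(fit$bd), byrow = TRUE)
}

.lstm_forward <- function(fit, X) {
  n <- nrow(X); T <- ncol(X); H <- ncol(fit$Wi)
  h <- matrix(0, n, H); cst <- matrix(0, n, H)
  for (s in seq_len(T)) {
    st <- lstm_cell_step(fit, X[, s], h, cst)
    h <- st$h; cst <- st$c
  }
  Z1 <- h %*% fit$Wd1 + matrix(fit$bd1, n, H, byrow = TRUE)
  A1 <- pmax(Z1, 0)
  A1 %*% fit$Wd2 + matrix(fit$bd2, n, ncol(fit$Wd2), byrow = TRUE)
}

#' Predict corrected velocities
#'
#' @param object A fitted `af_model`.
#' @param newdata A `sample_table`, data frame, or 4-column matrix of
#'   features (u_ofm, v_ofm, Ix, Iy).
#' @param ... Unused.
#' @return n x 2 matrix of corrected (u, v) in m/s.
#' @export
predict.af_model <- function(object, newdata, ...) {
  if (is.null(object$fit)) stop("model is not fitted", call. = FALSE)
  X <- if (is.matrix(newdata)) newdata else .features(newdata)
  if (ncol(X) != 4) stop("expected 4 feature columns", call. = FALSE)
  Xs <- object$scaler$scale_x(X)
  Ys <- switch(object$kind,
    lasso = {
      pr <- stats::predict(object$fit$glmnet, newx = Xs, s = object$fit$lambda)
      matrix(pr[, , 1], nrow = nrow(Xs))
    },
    mlp = .mlp_forward(object$fit, Xs),
    cnn = .cnn_forward(object$fit, Xs),
    lstm = .lstm_forward(object$fit, Xs))
  out <- object$scaler$unscale_y(Ys)
  colnames(out) <- c("u", "v")
  out
}

#' @export
print.af_model <- function(x, ...) {
  cat(sprintf("<angioflow %s model> loss=%s epochs=%s seed=%d\n",
              toupper(x$kind), x$config$loss,
              if (x$kind == "lasso") "-" else x$config$epochs,
              x$config$seed))
  if (!is.null(x$history))
    cat(sprintf("  final training loss (scaled units): %.6g\n",
                utils::tail(x$history, 1)))
  invisible(x)
}

#' LASSO coefficients on the standardized scale
#'
#' @param object An `af_model` of kind `"lasso"`.
#' @param ... Unused.
#' @return 5 x 2 matrix (intercept + 4 features, per output).
#' @export
coef.af_lasso <- function(object, ...) {
  cf <- glmnet::coef.glmnet(object$fit$glmnet, s = object$fit$lambda)
  do.call(cbind, lapply(cf, function(m) as.matrix(m)[, 1]))
}

.fit_model <- function(kind, table, config) {
  switch(kind,
         lasso = fit_lasso(table, config = config),
         mlp = fit_mlp(table, config),
         cnn = fit_cnn(table, config),
         lstm = fit_lstm(table, config))
}

#' Fit one model by config
#'
#' @param table A `sample_table`.
#' @param config A [model_config()].
#' @return An `af_model`.
#' @export
fit_model <- function(table, config) .fit_model(config$kind, table, config)

#' Repeated k-fold cross-validation
#'
#' Shuffles the table (seeded), partitions it into `k` folds, trains on
#' k-1 folds and scores MAE and MSE (pooled over the u and v outputs, in
#' m/s) on the held-out fold; repeated `repeats` times with fresh
#' shuffles.  Fold models use `seed + repeat` so refits are deterministic.
#'
#' @param config A [model_config()].
#' @param table A `sample_table`.
#' @param k Number of folds (default 10).
#' @param repeats Number of repeats (default 3).
#' @param seed Integer seed for the fold shuffles.
#' @return Object of class `cv_scores`: data.frame (repeat, fold, mae,
#'   mse) with attributes `mean_mae`, `sd_mae`, `mean_mse`, `sd_mse`.
#' @export
cross_validate <- function(config, table, k = 10, repeats = 3, seed = 1L) {
  n <- nrow(table)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  rng <- .seeded_rng(seed)
  res <- list()
  for (r in seq_len(repeats)) {
    ord <- order(rng$rnorm(n))
    fold_id <- integer(n)
    fold_id[ord] <- rep(seq_len(k), length.out = n)
    for (f in seq_len(k)) {
      test_idx <- which(fold_id == f)
      tr <- table[-test_idx, , drop = FALSE]
      te <- table[test_idx, , drop = FALSE]
      tr$split <- "train"
      cfg <- config
      cfg$seed <- config$seed + r
      mod <- .fit_model(config$kind, tr, cfg)
      pred <- predict(mod, te)
      truth <- .targets(te)
      res[[length(res) + 1L]] <- data.frame(
        rep = r, fold = f,
        mae = mae(pred, truth), mse = mse(pred, truth))
    }
  }
  out <- do.call(rbind, res)
  attr(out, "mean_mae") <- mean(out$mae)
  attr(out, "sd_mae") <- stats::sd(out$mae)
  attr(out, "mean_mse") <- mean(out$mse)
  attr(out, "sd_mse") <- stats::sd(out$mse)
  attr(out, "kind") <- config$kind
  attr(out, "loss") <- config$loss
  class(out) <- c("cv_scores", class(out))
  out
}

#' Save / load a fitted model
#'
#' Models serialize with their scaler and config and reload
#' bit-compatibly: predictions before and after a round trip are
#' identical.
#'
#' @param model An `af_model`.
#' @param path Destination file.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
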