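# Small feed-forward neural networks (one hidden layer) trained by
# quasi-Newton (BFGS) minimization of sum-of-squares error with quadratic
# weight decay and early stopping on a held-out test subset.

.activations <- list(
  identity    = list(f = function(z) z,            df = function(z) rep(1, length(z))),
  logistic    = list(f = function(z) 1 / (1 + exp(-z)),
                     df = function(z) { s <- 1 / (1 + exp(-z)); s * (1 - s) }),
  tanh        = list(f = function(z) tanh(z),      df = function(z) 1 - tanh(z)^2),
  exponential = list(f = function(z) exp(pmin(z, 30)),
                     df = function(z) exp(pmin(z, 30)))
)

#' Activation functions available for network layers
#' @return Character vector of activation codes.
#' @export
ann_activations <- function() names(.activations)

# target range for the scaled response, per output activation
.y_range_for <- function(act) {
  switch(act, logistic = c(0.1, 0.9), tanh = c(-0.8, 0.8),
         exponential = c(0.1, 0.9), identity = c(0.1, 0.9))
}

.minmax_fit <- function(x) {
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  rg <- hi - lo; rg[rg == 0] <- 1
  list(lo = lo, rg = rg)
}
.minmax_apply <- function(x, sc) sweep(sweep(x, 2, sc$lo), 2, sc$rg, "/")

.unpack <- function(w, d, h) {
  i <- 0
  W1 <- matrix(w[i + seq_len(h * d)], h, d); i <- i + h * d
  b1 <- w[i + seq_len(h)]; i <- i + h
  W2 <- w[i + seq_len(h)]; i <- i + h
  b2 <- w[i + 1]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

.forward <- function(par, X, act_h, act_o) {
  Z1 <- X %*% t(par$W1) + matrix(par$b1, nrow(X), length(par$b1), byrow = TRUE)
  H <- .activations[[act_h]]$f(Z1)
  z2 <- drop(H %*% par$W2) + par$b2
  list(Z1 = Z1, H = H, z2 = z2, out = .activations[[act_o]]$f(z2))
}

#' Train a single feed-forward network
#'
#' Trains a one-hidden-layer perceptron for a continuous response by BFGS
#' minimization of the sum-of-squares error plus quadratic weight-decay
#' penalties (`decay_hidden * ||W1||^2 + decay_output * ||W2||^2`, biases
#' unpenalized). Inputs are min-max scaled to [0, 1]; the response is
#' min-max scaled into the output activation's comfortable range and
#' back-transformed at prediction time.
#'
#' Training proceeds in short BFGS segments; after each segment the error
#' on the test subset (if given) is evaluated and the weights achieving
#' the lowest test error are kept (early stopping).
#'
#' @param x,y Training inputs (matrix) and response.
#' @param hidden Number of hidden units.
#' @param act_hidden,act_output Activation codes, see [ann_activations()].
#' @param decay_hidden,decay_output Weight-decay coefficients.
#' @param test_x,test_y Held-out test subset monitored for early stopping.
#' @param segments,segment_iter Number of BFGS segments and iterations per
#'   segment (total iteration cap = `segments * segment_iter`).
#' @param init_sd Standard deviation of the normal weight initialization.
#' @param seed Optional seed applied before initialization.
#' @return An object of class `qsrr_ann` with weights, scaling, training
#'   `history` (per-segment train/test error) and configuration.
#' @export
train_ann <- function(x, y, hidden, act_hidden = "tanh",
                      act_output = "identity",
                      decay_hidden = 0.01, decay_output = 0.01,
                      test_x = NULL, test_y = NULL,
                      segments = 15, segment_iter = 20,
                      init_sd = 0.5, seed = NULL) {
  x <- as.matrix(x)
  act_hidden <- match.arg(act_hidden, names(.activations))
  act_output <- match.arg(act_output, names(.activations))
  if (!is.null(seed)) set.seed(seed)
  d <- ncol(x); n <- nrow(x)
  xsc <- .minmax_fit(x)
  ylo <- min(y); yrg <- max(y) - min(y); if (yrg == 0) yrg <- 1
  trg <- .y_range_for(act_output)
  scale_y <- function(v) trg[1] + (v - ylo) / yrg * (trg[2] - trg[1])
  unscale_y <- function(t) ylo + (t - trg[1]) / (trg[2] - trg[1]) * yrg
  Xs <- .minmax_apply(x, xsc)
  t_train <- scale_y(y)
  Xt <- if (!is.null(test_x)) .minmax_apply(as.matrix(test_x), xsc)
  t_test <- if (!is.null(test_y)) scale_y(test_y)

  npar <- hidden * d + hidden + hidden + 1
  w0 <- rnorm(npar, sd = init_sd)
  loss_grad <- function(w) {
    par <- .unpack(w, d, hidden)
    fw <- .forward(par, Xs, act_hidden, act_output)
    err <- fw$out - t_train
    loss <- sum(err^2) + decay_hidden * sum(par$W1^2) +
      decay_output * sum(par$W2^2)
    dz2 <- 2 * err * .activations[[act_output]]$df(fw$z2)
    gW2 <- drop(crossprod(fw$H, dz2)) + 2 * decay_output * par$W2
    gb2 <- sum(dz2)
    dH <- outer(dz2, par$W2)
    dZ1 <- dH * .activations[[act_hidden]]$df(fw$Z1)
    gW1 <- crossprod(dZ1, Xs) + 2 * decay_hidden * par$W1
    gb1 <- colSums(dZ1)
    list(loss = loss, grad = c(as.vector(gW1), gb1, gW2, gb2))
  }
  sse_scaled <- function(w, X, t) {
    par <- .unpack(w, d, hidden)
    mean((.forward(par, X, act_hidden, act_output)$out - t)^2)
  }

  w <- w0
  best_w <- w
  best_test <- Inf
  history <- data.frame(segment = integer(0), train_error = numeric(0),
                        test_error = numeric(0))
  for (s in seq_len(segments)) {
    opt <- optim(w, fn = function(w) loss_grad(w)$loss,
                 gr = function(w) loss_grad(w)$grad,
                 method = "BFGS", control = list(maxit = segment_iter))
    w <- opt$par
    tr_err <- sse_scaled(w, Xs, t_train)
    te_err <- if (!is.null(Xt)) sse_scaled(w, Xt, t_test) else NA_real_
    history[nrow(history) + 1, ] <- list(s, tr_err, te_err)
    if (!is.null(Xt)) {
      if (te_err < best_test) { best_test <- te_err; best_w <- w }
    } else best_w <- w
    if (opt$convergence == 0 && s > 1) break
  }
  structure(list(
    weights = best_w, hidden = hidden, d = d,
    act_hidden = act_hidden, act_output = act_output,
    decay_hidden = decay_hidden, decay_output = decay_output,
    x_scaling = xsc, y_lo = ylo, y_rg = yrg, target_range = trg,
    history = history, seed = seed,
    descriptors = colnames(x),
    train_error = sse_scaled(best_w, Xs, t_train),
    test_error = if (!is.null(Xt)) sse_scaled(best_w, Xt, t_test) else NA_real_,
    train_x = x, train_y = y
  ), class = "qsrr_ann")
}

#' @export
print.qsrr_ann <- function(x, ...) {
  cat("QSRR neural network: ", x$d, "-", x$hidden, "-1 (",
      x$act_hidden, "/", x$act_output, "), decay ",
      x$decay_hidden, "/", x$decay_output, "\n",
      "train error ", format(x$train_error, digits = 4),
      if (!is.na(x$test_error))
        paste0(", test error ", format(x$test_error, digits = 4)),
      "\n", sep = "")
  invisible(x)
}

#' Predict from a trained network
#'
#' @param object A `qsrr_ann`.
#' @param newdata Matrix/data frame with the training input columns.
#' @param ... Unused.
#' @return Predicted response on the original scale.
#' @export
predict.qsrr_ann <- function(object, newdata, ...) {
  if (missing(newdata)) newdata <- object$train_x
  newdata <- as.data.frame(newdata)
  if (!is.null(object$descriptors)) {
    missing_cols <- setdiff(object$descriptors, colnames(newdata))
    if (length(missing_cols))
      stop("missing descriptor column(s): ",
           paste(missing_cols, collapse = ", "))
    newdata <- newdata[, object$descriptors, drop = FALSE]
  }
  X <- .minmax_apply(as.matrix(newdata), object$x_scaling)
  par <- .unpack(object$weights, object$d, object$hidden)
  out <- .forward(par, X, object$act_hidden, object$act_output)$out
  trg <- object$target_range
  object$y_lo + (out - trg[1]) / (trg[2] - trg[1]) * object$y_rg
}

#' Network error on a dataset
#'
#' Mean squared error on the scaled response, the quantity monitored for
#' early stopping and stored in the training history.
#'
#' @param object A `qsrr_ann`.
#' @param x,y Inputs and response.
#' @return Mean squared error on the scaled target.
#' @export
ann_error <- function(object, x, y) {
  X <- .minmax_apply(as.matrix(x), object$x_scaling)
  par <- .unpack(object$weights, object$d, object$hidden)
  out <- .forward(par, X, object$act_hidden, object$act_output)$out
  trg <- object$target_range
  t <- trg[1] + (y - object$y_lo) / object$y_rg * (trg[2] - trg[1])
  mean((out - t)^2)
}

#' Train an ensemble of random-architecture networks
#'
#' Trains `n_networks` networks with architecture drawn at random from the
#' search space (hidden units and hidden/output activation pairs) and
#' normal random weight initialization, each early-stopped on the test
#' subset, and returns the best network plus a leaderboard.
#'
#' By default the network with the smallest test-subset error is selected.
#' `select_on = "validation"` instead selects on the external validation
#' subset, reproducing the published protocol; note this lets the
#' validation set influence model choice, so validation statistics of the
#' selected model are no longer strictly external.
#'
#' @param x,y Full input matrix and response.
#' @param split Character vector over rows with labels `"train"`,
#'   `"test"` and (optionally) `"validation"`.
#' @param hidden_range Candidate hidden-unit counts (default 3:8).
#' @param activations Candidate activation codes for both layers.
#' @param n_networks Number of networks to train (default 500).
#' @param decay_hidden,decay_output Weight-decay coefficients.
#' @param select_on `"test"` (default) or `"validation"`.
#' @param seed Seed controlling all architecture draws and
#'   initializations; network i is reproducible from (seed, i).
#' @param ... Passed to [train_ann()] (e.g. `segments`).
#' @return An object of class `qsrr_ann_ensemble`: list with `best` (a
#'   `qsrr_ann`), `leaderboard` (one row per network) and the
#'   configuration.
#' @export
train_ann_ensemble <- function(x, y, split, hidden_range = 3:8,
                               activations = ann_activations(),
                               n_networks = 500,
                               decay_hidden = 0.01, decay_output = 0.01,
                               select_on = c("test", "validation"),
                               seed = 1, ...) {
  select_on <- match.arg(select_on)
  x <- as.matrix(x)
  stopifnot(length(split) == nrow(x), length(y) == nrow(x))
  if (!any(split == "test"))
    stop("early stopping requires a non-empty test subset")
  if (select_on == "validation") {
    if (!any(split == "validation"))
      stop("select_on = 'validation' requires validation rows")
    warning("selecting on the validation subset reproduces the published ",
            "protocol but leaks the validation set into model choice")
  }
  tr <- split == "train"; te <- split == "test"; va <- split == "validation"
  set.seed(seed)
  net_seeds <- sample.int(.Machine$integer.max - 1, n_networks)
  lb <- data.frame(network = integer(0), hidden = integer(0),
                   act_hidden = character(0), act_output = character(0),
                   train_error = numeric(0), test_error = numeric(0),
                   validation_error = numeric(0))
  best <- NULL; best_score <- Inf
  for (i in seq_len(n_networks)) {
    set.seed(net_seeds[i])
    h <- sample(hidden_range, 1)
    ah <- sample(activations, 1)
    ao <- sample(activations, 1)
    net <- train_ann(x[tr, , drop = FALSE], y[tr], hidden = h,
                     act_hidden = ah, act_output = ao,
                     decay_hidden = decay_hidden,
                     decay_output = decay_output,
                     test_x = x[te, , drop = FALSE], test_y = y[te], ...)
    ve <- if (any(va)) ann_error(net, x[va, , drop = FALSE], y[va]) else NA_real_
    lb[nrow(lb) + 1, ] <- list(i, h, ah, ao, net$train_error,
                               net$test_error, ve)
    score <- if (select_on == "test") net$test_error else ve
    if (score < best_score) { best_score <- score; best <- net }
  }
  structure(list(best = best, leaderboard = lb, select_on = select_on,
                 seed = seed, n_networks = n_networks),
            class = "qsrr_ann_ensemble")
}

#' @export
print.qsrr_ann_ensemble <- function(x, ...) {
  cat("ANN ensemble: ", x$n_networks, " networks, selected on ",
      x$select_on, " error\nbest network:\n", sep = "")
  print(x$best)
  invisible(x)
}

#' Global sensitivity ranking of network inputs
#'
#' Ranks inputs by the error ratio obtained when each input is replaced by
#' its training mean: ratio_k = SSE(input k held at its mean) / SSE(intact).
#' Inputs the network relies on get large ratios; an ignored input gets
#' ratio 1.
#'
#' @param object A `qsrr_ann`.
#' @param x,y Data to evaluate on (default: the network's training data).
#' @return Data frame (descriptor, ratio) sorted by decreasing ratio.
#' @export
sensitivity_ranking <- function(object, x = object$train_x,
                                y = object$train_y) {
  x <- as.matrix(x)
  base <- ann_error(object, x, y)
  ratios <- vapply(seq_len(ncol(x)), function(k) {
    xk <- x
    xk[, k] <- mean(object$train_x[, k])
    ann_error(object, xk, y) / base
  }, numeric(1))
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("V", seq_len(ncol(x)))
  out <- data.frame(descriptor = nms, ratio = ratios,
                    stringsAsFactors = FALSE)
  out[order(-out$ratio), , drop = FALSE]
}
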