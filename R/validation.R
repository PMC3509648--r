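# Model validation: PRESS / Q-squared, leave-one-out cross-validation,
# external validation and y-scrambling.

#' Predictive residual sum of squares (PRESS)
#'
#' Sum of squared prediction errors over a set of compounds.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return A single non-negative number.
#' @export
#' @examples
#' press(c(1, 2), c(2, 4))  # 5
press <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have the same length")
  if (length(observed) < 1) stop("need at least one observation")
  sum((predicted - observed)^2)
}

#' Validation coefficient of determination (Q-squared)
#'
#' Q2 = 1 - PRESS / sum((y - reference_mean)^2). The reference mean is,
#' by convention here, the mean of the training-set responses, so that
#' internal and external validation share the same standard reference;
#' pass the validation-set mean instead to use the alternative convention.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @param reference_mean Reference mean (usually the training mean).
#' @return A single number, at most 1.
#' @export
q2 <- function(observed, predicted, reference_mean) {
  denom <- sum((observed - reference_mean)^2)
  if (denom == 0) stop("zero denominator: observations equal the reference mean")
  1 - press(observed, predicted) / denom
}

#' Leave-one-out cross-validation
#'
#' For each row, refits the model on the remaining n - 1 rows and predicts
#' the held-out row (an explicit refit loop, no shortcut). Internal PRESS
#' and Q2 use the full-sample mean as reference.
#'
#' @param x Descriptor matrix (n x p).
#' @param y Response vector.
#' @param fitter Function `(x, y) -> model` whose result supports
#'   `predict(model, newdata)`; defaults to [fit_ols()].
#' @return An object of class `qsrr_validation`: list with `press_int`,
#'   `q2_int`, `reference_mean`, and a per-compound data frame `table`
#'   (observed, predicted, residual).
#' @export
loo_cv <- function(x, y, fitter = fit_ols) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("leave-one-out needs at least 3 rows")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  pred <- vapply(seq_len(n), function(i) {
    model <- tryCatch(fitter(x[-i, , drop = FALSE], y[-i]),
                      error = function(e)
                        stop("fitter failed on fold ", i, ": ",
                             conditionMessage(e), call. = FALSE))
    as.numeric(predict(model, x[i, , drop = FALSE]))
  }, numeric(1))
  ref <- mean(y)
  structure(list(
    press_int = press(y, pred), q2_int = q2(y, pred, ref),
    reference_mean = ref,
    table = data.frame(observed = y, predicted = pred,
                       residual = pred - y)
  ), class = "qsrr_validation")
}

#' External validation of model predictions
#'
#' Computes PRESS and Q2 on the external validation rows of a labelled
#' split, using the training-set mean as the Q2 reference (the shared
#' standard-reference convention); optionally the validation-set mean.
#'
#' @param predicted Predictions for all rows (or at least the validation
#'   rows, in row order).
#' @param split Character labels per row: `"train"`, `"test"`,
#'   `"validation"`. Test rows (the early-stopping subset) count as part
#'   of the training set for the reference mean.
#' @param observed Observed response for all rows.
#' @param reference `"train"` (default) or `"validation"`.
#' @return A `qsrr_validation` object with `press_ext`, `q2_ext`,
#'   `reference_mean` and the per-compound `table`.
#' @export
external_validate <- function(predicted, split, observed,
                              reference = c("train", "validation")) {
  reference <- match.arg(reference)
  if (length(predicted) != length(observed) ||
      length(split) != length(observed))
    stop("predicted, observed and split must align row-for-row")
  va <- split == "validation"
  if (!any(va)) stop("no validation rows in split")
  ref <- if (reference == "train") mean(observed[!va]) else mean(observed[va])
  obs_v <- observed[va]; pred_v <- predicted[va]
  structure(list(
    press_ext = press(obs_v, pred_v), q2_ext = q2(obs_v, pred_v, ref),
    reference_mean = ref, reference = reference,
    table = data.frame(observed = obs_v, predicted = pred_v,
                       residual = pred_v - obs_v)
  ), class = "qsrr_validation")
}

#' @export
print.qsrr_validation <- function(x, ...) {
  if (!is.null(x$press_int))
    cat(sprintf("internal: PRESS = %.4f, Q2 = %.4f\n", x$press_int, x$q2_int))
  if (!is.null(x$press_ext))
    cat(sprintf("external: PRESS = %.4f, Q2 = %.4f (reference mean %.4f)\n",
                x$press_ext, x$q2_ext, x$reference_mean))
  invisible(x)
}

#' y-scrambling (response randomization) diagnostic
#'
#' Refits the model on permuted responses to bound chance correlation.
#' The descriptor subset is held fixed (coefficients are refit per
#' permutation; variable selection is not rerun). For each permutation
#' the scrambled-model R2 and the absolute correlation between permuted
#' and observed responses are recorded, and a least-squares line of R2 on
#' that correlation is fitted; a small intercept indicates the original
#' fit is not a chance correlation.
#'
#' @param x Descriptor matrix (the already-selected subset).
#' @param y Response.
#' @param fitter Function `(x, y) -> model` with an `r_squared` element or
#'   whose predictions define R2; defaults to [fit_ols()].
#' @param n_permutations Number of permutations (>= 10; default 500).
#' @param seed Seed for the permutations.
#' @return An object of class `qsrr_scrambling`: data frame `table`
#'   (r2_scrambled, abs_correlation), `intercept`, `slope`,
#'   `mean_r2`, `original_r2`, `seed`, `n_permutations`.
#' @export
y_scramble <- function(x, y, fitter = fit_ols, n_permutations = 500,
                       seed = 1) {
  if (n_permutations < 10) stop("need at least 10 permutations")
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  r2_of <- function(model, yy) {
    if (!is.null(model$r_squared)) return(model$r_squared)
    pred <- as.numeric(predict(model, x))
    1 - sum((yy - pred)^2) / sum((yy - mean(yy))^2)
  }
  set.seed(seed)
  r2s <- numeric(n_permutations); cors <- numeric(n_permutations)
  for (k in seq_len(n_permutations)) {
    yp <- sample(y)
    r2s[k] <- r2_of(fitter(x, yp), yp)
    cors[k] <- abs(cor(yp, y))
  }
  line <- lm.fit(cbind(1, cors), r2s)$coefficients
  structure(list(
    table = data.frame(r2_scrambled = r2s, abs_correlation = cors),
    intercept = line[[1]], slope = line[[2]],
    mean_r2 = mean(r2s), original_r2 = r2_of(fitter(x, y), y),
    seed = seed, n_permutations = n_permutations
  ), class = "qsrr_scrambling")
}

#' @export
print.qsrr_scrambling <- function(x, ...) {
  cat(sprintf(paste0("y-scrambling (%d permutations): mean scrambled R2 = ",
                     "%.3f, line intercept = %.3f (original R2 = %.3f)\n"),
              x$n_permutations, x$mean_r2, x$intercept, x$original_r2))
  invisible(x)
}

#' @export
plot.qsrr_scrambling <- function(x, ...) {
  plot(x$table$abs_correlation, x$table$r2_scrambled,
       xlab = "|cor(permuted y, observed y)|", ylab = "scrambled R2",
       main = "y-scrambling diagnostic", xlim = c(0, 1),
       ylim = range(c(x$table$r2_scrambled, x$original_r2)), ...)
  abline(x$intercept, x$slope, lty = 2)
  points(1, x$original_r2, pch = 19)
  invisible(x)
}
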