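# Ordinary least squares with coefficient inference on (optionally)
# standardized descriptors.

#' Fit an ordinary least-squares retention model
#'
#' Fits y on a descriptor matrix by least squares, by default after
#' standardizing each descriptor to zero mean and unit variance (the
#' convention used throughout the modelling layer; coefficients are then
#' on the standardized scale). Standardization parameters are stored so
#' the model predicts directly from raw descriptor values.
#'
#' @param x Numeric matrix (n x p) with descriptor column names.
#' @param y Numeric response (retention times, minutes).
#' @param standardize Standardize columns before fitting?
#' @return An object of class `qsrr_lm`: coefficients, standard errors,
#'   `t` and two-sided `p` values (Student t, n-p-1 df), `r_squared`,
#'   residuals, fitted values and the scaling parameters.
#' @export
#' @examples
#' x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- 2 * x[, 1] - x[, 2] + rnorm(20, sd = 0.1)
#' fit <- fit_ols(x, y)
#' coef(fit)
fit_ols <- function(x, y, standardize = TRUE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  if (n <= p + 1) stop("need n > p + 1 observations")
  center <- if (standardize) colMeans(x) else rep(0, p)
  scale_ <- if (standardize) apply(x, 2, sd) else rep(1, p)
  if (any(scale_ == 0)) stop("constant column(s): ",
                             paste(colnames(x)[scale_ == 0], collapse = ", "))
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  design <- cbind(`(Intercept)` = 1, xs)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dep <- setdiff(colnames(design), colnames(design)[qrd$pivot[seq_len(qrd$rank)]])
    stop("design matrix is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  fit <- lm.fit(design, y)
  beta <- fit$coefficients
  res <- fit$residuals
  df <- n - p - 1
  sse <- sum(res^2)
  sigma2 <- sse / df
  xtx_inv <- chol2inv(qr.R(qrd))
  se <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- names(beta)
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  sst <- sum((y - mean(y))^2)
  structure(list(
    descriptors = colnames(x),
    coefficients = beta[-1], intercept = beta[[1]],
    se = se[-1], se_intercept = se[[1]],
    t = tval[-1], p = pval[-1],
    n = n, df = df, r_squared = 1 - sse / sst, sigma = sqrt(sigma2),
    residuals = res, fitted = fit$fitted.values, y = y,
    center = center, scale = scale_, standardize = standardize,
    call = match.call()
  ), class = "qsrr_lm")
}

#' @export
print.qsrr_lm <- function(x, digits = 4, ...) {
  cat("QSRR linear model (", length(x$descriptors), " descriptors, n = ",
      x$n, ")\n", sep = "")
  cat("RT =", paste(sprintf("%+.*f %s", digits, x$coefficients,
                            x$descriptors), collapse = " "),
      sprintf("%+.*f", digits, x$intercept), "\n")
  cat("R2 =", format(x$r_squared, digits = digits), "\n")
  invisible(x)
}

#' @export
summary.qsrr_lm <- function(object, ...) {
  tab <- data.frame(
    estimate = c(object$coefficients, `(Intercept)` = object$intercept),
    se = c(object$se, object$se_intercept),
    t = c(object$t, object$intercept / object$se_intercept))
  tab$p <- 2 * pt(abs(tab$t), object$df, lower.tail = FALSE)
  structure(list(coefficients = tab, r_squared = object$r_squared,
                 sigma = object$sigma, n = object$n, df = object$df),
            class = "summary.qsrr_lm")
}

#' @export
print.summary.qsrr_lm <- function(x, ...) {
  printCoefmat(as.matrix(x$coefficients), P.values = TRUE, has.Pvalue = TRUE)
  cat("\nn =", x$n, " residual df =", x$df,
      " R2 =", format(x$r_squared, digits = 4),
      " sigma =", format(x$sigma, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.qsrr_lm <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
residuals.qsrr_lm <- function(object, ...) object$residuals

#' Predict retention times from a linear model
#'
#' Applies the stored standardization and coefficients to new raw
#' descriptor values.
#'
#' @param object A `qsrr_lm` model.
#' @param newdata Matrix or data frame containing the model's descriptor
#'   columns (any extra columns are ignored).
#' @param ... Unused.
#' @return Numeric vector of predicted retention times (minutes).
#' @export
predict.qsrr_lm <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$descriptors, colnames(newdata))
  if (length(missing_cols))
    stop("missing descriptor column(s): ", paste(missing_cols, collapse = ", "))
  newdata <- as.matrix(newdata[, object$descriptors, drop = FALSE])
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  drop(xs %*% object$coefficients + object$intercept)
}

#' @export
plot.qsrr_lm <- function(x, ...) {
  plot(x$fitted, x$y, xlab = "Predicted RT (min)",
       ylab = "Observed RT (min)",
       main = sprintf("QSRR linear model (R2 = %.3f)", x$r_squared), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}
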