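# Stepwise multiple linear regression with partial-F entry/removal.

#' Stepwise multiple linear regression (SMLR)
#'
#' Classical forward-stepwise selection with backward checks on
#' standardized descriptors. At each step the candidate with the largest
#' partial F statistic,
#' F = (SSE_reduced - SSE_full) / (SSE_full / (n - p_full - 1)),
#' enters if F >= `f_enter`; after every entry, any included descriptor
#' whose partial F falls below `f_remove` is removed. The procedure stops
#' when no entry or removal changes the model.
#'
#' An entry is refused (and logged in the trace) when it would leave
#' fewer than two residual degrees of freedom (n <= p + 2) or make the
#' design matrix rank deficient, regardless of its F value.
#'
#' @param x Numeric matrix of candidate descriptors (named columns).
#' @param y Numeric response.
#' @param f_enter Partial-F threshold to enter (default 6).
#' @param f_remove Partial-F threshold to remove (default 3).
#' @return An object of class `smlr_result`: list with `trace` (data
#'   frame: step, action, descriptor, f, r_squared), `selected` (final
#'   descriptor names), `model` (a [fit_ols()] `qsrr_lm` on the final
#'   subset, or `NULL` when empty), and the thresholds.
#' @export
smlr <- function(x, y, f_enter = 6, f_remove = 3) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  n <- nrow(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  usable <- apply(x, 2, sd) > 0
  xs <- scale(x[, usable, drop = FALSE])
  cols <- colnames(xs)
  sst <- sum((y - mean(y))^2)

  sse_of <- function(set) {
    if (!length(set)) return(sst)
    d <- cbind(1, xs[, set, drop = FALSE])
    if (qr(d)$rank < ncol(d)) return(NA_real_)  # rank deficient
    sum(lm.fit(d, y)$residuals^2)
  }

  trace <- data.frame(step = integer(0), action = character(0),
                      descriptor = character(0), f = numeric(0),
                      r_squared = numeric(0), stringsAsFactors = FALSE)
  log_step <- function(action, descriptor, f, sse) {
    trace[nrow(trace) + 1, ] <<- list(nrow(trace) + 1, action, descriptor,
                                      f, 1 - sse / sst)
  }
  selected <- character(0)
  if (sst > 0) repeat {
    sse_cur <- sse_of(selected)
    candidates <- setdiff(cols, selected)
    if (!length(candidates)) break
    p_new <- length(selected) + 1
    if (n <= p_new + 2) {
      log_step("refuse", "(df exhausted)", NA_real_, sse_cur)
      break
    }
    fstat <- vapply(candidates, function(j) {
      sse_j <- sse_of(c(selected, j))
      if (is.na(sse_j)) return(NA_real_)  # would be rank deficient
      if (sse_j == 0) return(Inf)
      (sse_cur - sse_j) / (sse_j / (n - p_new - 1))
    }, numeric(1))
    if (all(is.na(fstat)) || max(fstat, na.rm = TRUE) < f_enter) break
    best <- candidates[which.max(fstat)]
    selected <- c(selected, best)
    sse_cur <- sse_of(selected)
    log_step("enter", best, max(fstat, na.rm = TRUE), sse_cur)
    # backward pass
    repeat {
      if (length(selected) < 2) break
      pf <- vapply(selected, function(k) {
        sse_red <- sse_of(setdiff(selected, k))
        if (sse_cur == 0) return(Inf)
        (sse_red - sse_cur) / (sse_cur / (n - length(selected) - 1))
      }, numeric(1))
      if (min(pf) >= f_remove) break
      worst <- selected[which.min(pf)]
      selected <- setdiff(selected, worst)
      sse_cur <- sse_of(selected)
      log_step("remove", worst, min(pf), sse_cur)
    }
    if (nrow(trace) > 4 * length(cols)) break  # cycle guard
  }
  model <- if (length(selected))
    fit_ols(x[, selected, drop = FALSE], y) else NULL
  structure(list(trace = trace, selected = selected, model = model,
                 f_enter = f_enter, f_remove = f_remove),
            class = "smlr_result")
}

#' @export
print.smlr_result <- function(x, ...) {
  cat("Stepwise MLR (F-to-enter = ", x$f_enter, ", F-to-remove = ",
      x$f_remove, ")\n", sep = "")
  if (nrow(x$trace)) print(x$trace, row.names = FALSE) else
    cat("  no descriptor entered\n")
  if (!is.null(x$model)) print(x$model)
  invisible(x)
}
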