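# Unsupervised forward selection: builds a maximal subset of descriptor
# columns whose mutual squared multiple correlation stays below R2max.

#' Unsupervised forward selection (UFS)
#'
#' Reduces a descriptor matrix to a linearly independent subset without
#' looking at the response. Columns are centred and scaled to unit norm;
#' the two columns with the smallest absolute pairwise correlation seed
#' the selection; then, repeatedly, the squared multiple correlation R2 of
#' every remaining column against the span of the selected ones is
#' computed by orthogonal projection, columns with R2 above `r2max` are
#' rejected permanently, and the column with the smallest R2 is admitted.
#' Selection stops when no admissible column remains.
#'
#' Ties (equal correlations or R2) are broken toward the lower original
#' column index, so the trace is reproducible and invariant to column
#' order. The projection basis is grown by modified Gram-Schmidt with
#' re-orthogonalization; a column whose residual norm falls below 1e-10 is
#' treated as exactly collinear (R2 = 1).
#'
#' @param x A `descriptor_matrix` or numeric matrix with column names.
#' @param r2max Maximum allowed squared multiple correlation of a selected
#'   column with the previously selected ones.
#' @return An object of class `ufs_result`: list with `selected` (ordered
#'   names), `rejected` (data frame: descriptor, r2 at rejection),
#'   `r2max`, `trace` (data frame of admissions with their R2).
#' @export
ufs <- function(x, r2max = 0.90) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (ncol(x) < 2) stop("UFS needs at least 2 columns")
  # drop near-constant columns (pretreatment normally removes them first)
  sds <- apply(x, 2, sd)
  near_const <- sds < 1e-8 * (abs(colMeans(x)) + 1)
  if (sum(!near_const) < 2) stop("fewer than 2 non-constant columns")
  keep_names <- colnames(x)[!near_const]
  z <- scale(x[, !near_const, drop = FALSE], center = TRUE, scale = FALSE)
  z <- sweep(z, 2, sqrt(colSums(z^2)), "/")
  p <- ncol(z)

  # seed: pair with smallest |correlation| (ties -> lowest index pair)
  cc <- abs(crossprod(z))
  diag(cc) <- Inf
  seed <- which(cc == min(cc), arr.ind = TRUE)
  seed <- seed[order(seed[, 1], seed[, 2]), , drop = FALSE][1, ]
  seed <- sort(seed)

  ortho <- function(q, v) {
    # residual of v after projection on columns of q (MGS, two passes)
    for (pass in 1:2) if (length(q)) {
      for (k in seq_along(q)) v <- v - sum(q[[k]] * v) * q[[k]]
    }
    v
  }
  basis <- list()
  add_to_basis <- function(v) {
    r <- ortho(basis, v)
    nr <- sqrt(sum(r^2))
    basis[[length(basis) + 1]] <<- r / nr
  }
  selected <- integer(0)
  trace_idx <- integer(0); trace_r2 <- numeric(0)
  rejected_idx <- integer(0); rejected_r2 <- numeric(0)
  for (s in seed) {
    selected <- c(selected, s)
    add_to_basis(z[, s])
    trace_idx <- c(trace_idx, s)
    trace_r2 <- c(trace_r2, if (length(trace_idx) == 1) 0 else cc[seed[1], seed[2]]^2)
  }
  remaining <- setdiff(seq_len(p), selected)
  while (length(remaining)) {
    r2 <- vapply(remaining, function(j) {
      r <- ortho(basis, z[, j])
      res2 <- sum(r^2)
      if (sqrt(res2) < 1e-10) 1 else max(0, 1 - res2)  # unit-norm column
    }, numeric(1))
    bad <- r2 > r2max
    rejected_idx <- c(rejected_idx, remaining[bad])
    rejected_r2 <- c(rejected_r2, r2[bad])
    remaining <- remaining[!bad]
    r2 <- r2[!bad]
    if (!length(remaining)) break
    pick <- which.min(r2)          # ties -> first, i.e. lowest index
    j <- remaining[pick]
    selected <- c(selected, j)
    trace_idx <- c(trace_idx, j); trace_r2 <- c(trace_r2, r2[pick])
    add_to_basis(z[, j])
    remaining <- remaining[-pick]
  }
  structure(list(
    selected = keep_names[trace_idx],
    rejected = data.frame(descriptor = keep_names[rejected_idx],
                          r2 = rejected_r2, stringsAsFactors = FALSE),
    r2max = r2max,
    trace = data.frame(descriptor = keep_names[trace_idx], r2 = trace_r2,
                       stringsAsFactors = FALSE)
  ), class = "ufs_result")
}

#' @export
print.ufs_result <- function(x, ...) {
  cat("Unsupervised forward selection (R2max = ", x$r2max, ")\n",
      "  selected ", length(x$selected), " descriptor(s): ",
      paste(x$selected, collapse = ", "), "\n",
      "  rejected ", nrow(x$rejected), " as collinear\n", sep = "")
  invisible(x)
}
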