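# Synthetic descriptor matrices with a planted sparse linear signal,
# blocks of near-collinear columns and additive Gaussian noise.

#' Specify a synthetic descriptor dataset
#'
#' Describes a compounds x descriptors matrix with the statistical
#' structure the modelling layer assumes: independent standard-normal
#' base columns, a sparse linear signal on the first `k` columns, and
#' designated columns replaced by noisy copies of parent columns with a
#' target squared correlation (emulating the collinearity that
#' unsupervised forward selection exists to remove).
#'
#' @param n Number of compounds (rows).
#' @param p Number of descriptors (columns).
#' @param k Number of informative columns (the first `k`).
#' @param beta Coefficient vector of length `k`.
#' @param n_copies Number of collinear copy columns (taken from the
#'   non-informative tail, cycling over parents 1..k and other columns).
#' @param copy_r2 Target squared correlation of each copy with its
#'   parent; scalar or length-`n_copies` vector (values in (0, 1)).
#' @param sigma Standard deviation of the additive response noise.
#' @param split Optional named integer vector `c(train=, test=,
#'   validation=)` summing to `n`; rows are labelled at generation time.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n, p, k, beta, n_copies = 0, copy_r2 = 0.95,
                       sigma = 1, split = NULL) {
  stopifnot(k <= p, length(beta) == k, sigma >= 0,
            all(copy_r2 > 0 & copy_r2 < 1),
            n_copies <= p - k)
  if (!is.null(split)) stopifnot(sum(split) == n,
                                 all(c("train", "test", "validation") %in%
                                       names(split)))
  structure(list(n = n, p = p, k = k, beta = beta, n_copies = n_copies,
                 copy_r2 = rep(copy_r2, length.out = n_copies),
                 sigma = sigma, split = split),
            class = "synth_spec")
}

#' Generate a synthetic descriptor dataset
#'
#' Draws the dataset described by a [synth_spec()]: base columns are
#' independent standard normal; copy columns are
#' `parent * sqrt(R2) + noise * sqrt(1 - R2)`; the response is
#' `X beta + Normal(0, sigma)` using the informative columns.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return List with `x` (matrix, columns `D1..Dp`), `y`, `split`
#'   (or `NULL`), and `truth` (informative column names, `beta`, the
#'   copy-parent map, `sigma`).
#' @export
#' @examples
#' d <- synth_generate(synth_spec(20, 10, 2, c(2, -1), sigma = 0.1), seed = 7)
#' str(d$truth)
synth_generate <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(seed)
  x <- matrix(rnorm(spec$n * spec$p), spec$n, spec$p,
              dimnames = list(NULL, paste0("D", seq_len(spec$p))))
  copies <- NULL
  if (spec$n_copies > 0) {
    copy_cols <- spec$p - spec$n_copies + seq_len(spec$n_copies)
    parents <- rep(seq_len(max(spec$k, 1)), length.out = spec$n_copies)
    for (i in seq_len(spec$n_copies)) {
      r2 <- spec$copy_r2[i]
      x[, copy_cols[i]] <- x[, parents[i]] * sqrt(r2) +
        rnorm(spec$n) * sqrt(1 - r2)
    }
    copies <- data.frame(copy = colnames(x)[copy_cols],
                         parent = colnames(x)[parents],
                         target_r2 = spec$copy_r2,
                         stringsAsFactors = FALSE)
  }
  y <- drop(x[, seq_len(spec$k), drop = FALSE] %*% spec$beta) +
    rnorm(spec$n, sd = spec$sigma)
  split <- NULL
  if (!is.null(spec$split)) {
    split <- sample(rep(c("train", "test", "validation"),
                        times = spec$split[c("train", "test", "validation")]))
  }
  list(x = x, y = y, split = split,
       truth = list(informative = colnames(x)[seq_len(spec$k)],
                    beta = spec$beta, copies = copies, sigma = spec$sigma))
}

#' Paper-like synthetic scenario
#'
#' A scenario mirroring the phenolics study's shape: 39 compounds split
#' 25/5/9 into train/test/validation, 100 descriptors of which 4 carry
#' the signal, coefficients scaled so the population R2 is about 0.95,
#' and 30 collinear copy columns at copy-parent R2 between 0.92 and 0.99.
#'
#' @return A [synth_spec()].
#' @export
paperlike_scenario <- function() {
  beta <- c(2, 1.5, 1, 0.5)
  # population R2 = sum(beta^2) / (sum(beta^2) + sigma^2) = 0.95
  sigma <- sqrt(sum(beta^2) * 0.05 / 0.95)
  synth_spec(n = 39, p = 100, k = 4, beta = beta, n_copies = 30,
             copy_r2 = seq(0.92, 0.99, length.out = 30), sigma = sigma,
             split = c(train = 25, test = 5, validation = 9))
}
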