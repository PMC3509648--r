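# Unsupervised forward selection and stepwise regression.

# brute-force squared multiple correlation of column j on a set of columns
brute_r2 <- function(x, j, on) {
  if (!length(on)) return(0)
  f <- lm.fit(cbind(1, x[, on, drop = FALSE]), x[, j])
  1 - sum(f$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
}

test_that("UFS keeps one of an exact duplicate pair and flags the other", {
  set.seed(5)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  x <- cbind(x, dup = x[, "a"])
  res <- ufs(x, 0.9)
  expect_true(xor("a" %in% res$selected, "dup" %in% res$selected))
  gone <- setdiff(c("a", "dup"), res$selected)
  expect_equal(res$rejected$r2[res$rejected$descriptor == gone], 1)
})

test_that("UFS selects everything when columns are orthogonal", {
  x <- qr.Q(qr(matrix(rnorm(100), 20, 5)))
  colnames(x) <- paste0("q", 1:5)
  res <- ufs(x, 0.9)
  expect_setequal(res$selected, colnames(x))
})

test_that("UFS agrees with a brute-force multiple-regression oracle", {
  # planted factor structure: 10 independent factors, 40 noisy copies
  for (seed in c(2, 7, 13)) {
    set.seed(seed)
    base <- matrix(rnorm(30 * 10), 30, 10)
    x <- base[, rep(1:10, 5)]
    x[, 11:50] <- sqrt(0.95) * x[, 11:50] +
      sqrt(0.05) * matrix(rnorm(30 * 40), 30, 40)
    colnames(x) <- paste0("c", 1:50)
    res <- ufs(x, 0.9)
    # every admission respected the threshold, verified by direct regression
    for (k in seq_along(res$selected)) {
      if (k <= 2) next
      expect_lte(brute_r2(x, res$selected[k],
                          res$selected[seq_len(k - 1)]), 0.9 + 1e-8)
    }
    # every rejection exceeds the threshold against the final selected set
    for (j in res$rejected$descriptor)
      expect_gt(brute_r2(x, j, res$selected), 0.9)
    # a representative of every factor survives
    for (f in 1:10) {
      members <- paste0("c", c(f, 10 + f, 20 + f, 30 + f, 40 + f))
      expect_true(any(members %in% res$selected), info = paste(seed, f))
    }
  }
})

test_that("UFS is deterministic and invariant to column order", {
  set.seed(31)
  x <- matrix(rnorm(25 * 8), 25, 8, dimnames = list(NULL, paste0("d", 1:8)))
  x[, 8] <- x[, 1] * sqrt(0.97) + rnorm(25) * sqrt(0.03)
  r1 <- ufs(x, 0.9)
  r2 <- ufs(x, 0.9)
  expect_identical(r1$trace, r2$trace)
  perm <- c(5, 2, 8, 1, 3, 7, 4, 6)
  r3 <- ufs(x[, perm], 0.9)
  expect_setequal(r3$selected, r1$selected)
  expect_error(ufs(x[, 1, drop = FALSE]), "at least 2")
  expect_error(ufs(cbind(a = rep(1, 10), b = rep(2, 10))), "non-constant")
})

test_that("SMLR handles exact and degenerate responses", {
  set.seed(4)
  x <- matrix(rnorm(25 * 6), 25, 6, dimnames = list(NULL, paste0("x", 1:6)))
  # y exactly one column: that column enters alone with a huge F
  res <- smlr(x, x[, 4])
  expect_identical(res$selected, "x4")
  expect_true(is.infinite(res$trace$f[1]) || res$trace$f[1] > 1e6)
  # constant y: nothing enters
  res0 <- smlr(x, rep(2.5, 25))
  expect_length(res0$selected, 0)
  expect_null(res0$model)
})

test_that("SMLR model R2 is non-decreasing over enter steps", {
  set.seed(12)
  x <- matrix(rnorm(40 * 12), 40, 12, dimnames = list(NULL, paste0("x", 1:12)))
  y <- x[, 1] - 2 * x[, 5] + 0.8 * x[, 9] + rnorm(40, sd = 0.5)
  res <- smlr(x, y)
  enters <- res$trace[res$trace$action == "enter", ]
  expect_true(all(diff(enters$r_squared) > -1e-12))
  expect_true(all(enters$f >= 6))
  rems <- res$trace[res$trace$action == "remove", ]
  if (nrow(rems)) expect_true(all(rems$f < 3))
})

test_that("SMLR recovers a planted sparse signal and matches best subset", {
  sigma <- sqrt(5 * 0.05 / 0.95)  # population R2 = 0.95 for beta (2, -1)
  recovered <- 0
  best_pair_hits <- 0
  n_rep <- 30
  for (seed in seq_len(n_rep)) {
    set.seed(seed)
    x <- matrix(rnorm(30 * 20), 30, 20,
                dimnames = list(NULL, paste0("x", 1:20)))
    y <- 2 * x[, 3] - x[, 7] + rnorm(30, sd = sigma)
    res <- smlr(x, y)
    if (all(c("x3", "x7") %in% res$selected)) recovered <- recovered + 1
    # exhaustive best subset of size 2
    best <- NULL; bsse <- Inf
    for (i in 1:19) for (j in (i + 1):20) {
      sse <- sum(lm.fit(cbind(1, x[, c(i, j)]), y)$residuals^2)
      if (sse < bsse) { bsse <- sse; best <- c(i, j) }
    }
    if (setequal(paste0("x", best), c("x3", "x7")))
      best_pair_hits <- best_pair_hits + 1
  }
  expect_gte(recovered, ceiling(0.95 * n_rep))
  expect_gte(best_pair_hits, ceiling(0.95 * n_rep))
})

test_that("SMLR refuses entries that would exhaust degrees of freedom", {
  set.seed(3)
  x <- matrix(rnorm(8 * 10), 8, 10, dimnames = list(NULL, paste0("x", 1:10)))
  y <- rnorm(8)
  res <- smlr(x, y, f_enter = 0.001)
  # n = 8 allows at most p with n > p + 2, i.e. 5 descriptors
  expect_lte(length(res$selected), 5)
})
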