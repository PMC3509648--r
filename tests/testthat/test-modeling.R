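# OLS with inference and the neural-network layer.

test_that("OLS reproduces exact relationships and guards rank", {
  set.seed(8)
  x <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- fit_ols(x, x[, "b"])
  expect_equal(unname(fit$coefficients["b"]) / sd(x[, "b"]), 1,
               tolerance = 1e-8)  # standardized coefficient scale
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(fit$residuals), rep(0, 20), tolerance = 1e-10)
  # noiseless recovery on a designed matrix, unstandardized
  q <- qr.Q(qr(matrix(rnorm(60), 20, 3))); colnames(q) <- c("a", "b", "c")
  beta <- c(2, -1, 0.5)
  fit2 <- fit_ols(q, drop(q %*% beta) + 1, standardize = FALSE)
  expect_equal(unname(fit2$coefficients), beta, tolerance = 1e-10)
  expect_equal(fit2$intercept, 1, tolerance = 1e-10)
  # rank deficiency is refused with the dependent column named
  xd <- cbind(x, d = x[, "a"] + x[, "b"])
  expect_error(fit_ols(xd, rnorm(20)), "rank deficient")
  expect_error(fit_ols(x[1:4, ], rnorm(4)), "n > p")
})

test_that("OLS matches the closed-form normal-equations oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 25; p <- 4
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    y <- rnorm(n)
    fit <- fit_ols(x, y, standardize = FALSE)
    d <- cbind(1, x)
    beta_hat <- solve(crossprod(d), crossprod(d, y))
    expect_equal(unname(c(fit$intercept, fit$coefficients)),
                 unname(drop(beta_hat)), tolerance = 1e-10)
    # reference-formula standard errors and T statistics
    res <- y - d %*% beta_hat
    s2 <- sum(res^2) / (n - p - 1)
    se <- sqrt(s2 * diag(solve(crossprod(d))))
    expect_equal(unname(fit$se), unname(se[-1]), tolerance = 1e-10)
    expect_equal(unname(fit$t),
                 unname(fit$coefficients) / unname(se[-1]),
                 tolerance = 1e-10)
  }
})

test_that("coefficient estimates are unbiased over replicates", {
  set.seed(99)
  beta <- c(1.5, -0.5, 0.8, 0)
  est <- replicate(200, {
    x <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("v", 1:4)))
    y <- drop(x %*% beta) + rnorm(30)
    unname(fit_ols(x, y, standardize = FALSE)$coefficients)
  })
  bias <- rowMeans(est) - beta
  sem <- apply(est, 1, sd) / sqrt(ncol(est))
  expect_true(all(abs(bias) < 3 * sem + 1e-8))
})

test_that("linear-model predictions respect the stored standardization", {
  set.seed(10)
  x <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("HNar", "DISPe")))
  y <- 3 + 2 * x[, 1] - x[, 2] + rnorm(30, sd = 0.1)
  fit <- fit_ols(x, y)
  expect_equal(predict(fit, x), unname(fit$fitted), ignore_attr = TRUE)
  # a row at the training means predicts the intercept
  at_mean <- matrix(colMeans(x), 1, dimnames = list(NULL, colnames(x)))
  expect_equal(unname(predict(fit, at_mean)), fit$intercept)
  # hand-computed prediction for a hand-built row
  row <- matrix(c(1.6, 0.3), 1, dimnames = list(NULL, colnames(x)))
  hand <- fit$intercept +
    sum(fit$coefficients * (c(1.6, 0.3) - fit$center) / fit$scale)
  expect_equal(unname(predict(fit, row)), hand)
  expect_error(predict(fit, matrix(1, 1, 1, dimnames = list(NULL, "HNar"))),
               "missing descriptor")
})

test_that("an identity-activation zero-decay network reaches the OLS fit", {
  set.seed(42)
  x <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + 2 * x[, 1] - x[, 2] + 0.5 * x[, 3] + rnorm(30, sd = 0.2)
  net <- train_ann(x, y, hidden = 4, act_hidden = "identity",
                   act_output = "identity", decay_hidden = 0,
                   decay_output = 0, seed = 7, segments = 30,
                   segment_iter = 50)
  ols <- fit_ols(x, y)
  rmse <- sqrt(mean((predict(net, x) - predict(ols, x))^2))
  expect_lt(rmse, 1e-3)
})

test_that("networks fit constants and are reproducible by seed", {
  set.seed(2)
  x <- matrix(rnorm(20 * 2), 20, 2, dimnames = list(NULL, c("a", "b")))
  net <- train_ann(x, rep(3.3, 20), hidden = 3, seed = 5, segments = 5)
  expect_equal(unname(predict(net, x)), rep(3.3, 20), tolerance = 1e-4)
  expect_lt(net$train_error, 1e-6)
  # ensemble determinism
  y <- x[, 1] + rnorm(20, sd = 0.3)
  split <- rep(c("train", "test"), c(15, 5))
  e1 <- train_ann_ensemble(x, y, split, n_networks = 4, seed = 11,
                           segments = 3)
  e2 <- train_ann_ensemble(x, y, split, n_networks = 4, seed = 11,
                           segments = 3)
  expect_identical(e1$leaderboard, e2$leaderboard)
  expect_error(train_ann_ensemble(x, y, rep("train", 20), n_networks = 2),
               "test subset")
})

test_that("weight decay shrinks weights and predictions monotonically", {
  set.seed(6)
  x <- matrix(rnorm(25 * 2), 25, 2, dimnames = list(NULL, c("a", "b")))
  y <- 2 * x[, 1] + rnorm(25, sd = 0.2)
  norms <- sapply(c(0.001, 0.1, 10, 1000), function(dec) {
    net <- train_ann(x, y, hidden = 3, act_hidden = "tanh",
                     act_output = "identity", decay_hidden = dec,
                     decay_output = dec, seed = 9, segments = 10)
    par <- qsrr:::.unpack(net$weights, 2, 3)
    sqrt(sum(par$W1^2) + sum(par$W2^2))
  })
  expect_true(all(diff(norms) < 0))
})

test_that("early stopping keeps the best test-error weights", {
  set.seed(14)
  x <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- x[, 1] - x[, 2] + rnorm(30, sd = 0.3)
  net <- train_ann(x[1:24, ], y[1:24], hidden = 6, test_x = x[25:30, ],
                   test_y = y[25:30], seed = 3, segments = 10)
  expect_lte(net$test_error,
             net$history$test_error[nrow(net$history)] + 1e-12)
  expect_equal(net$test_error, ann_error(net, x[25:30, ], y[25:30]),
               tolerance = 1e-12)
})

test_that("sensitivity ranking orders inputs by reliance", {
  set.seed(20)
  x <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 3 * x[, 1] + 1 * x[, 2] + 0.5 * x[, 3] + rnorm(40, sd = 0.1)
  net <- train_ann(x, y, hidden = 4, act_hidden = "identity",
                   act_output = "identity", decay_hidden = 0,
                   decay_output = 0, seed = 4, segments = 20)
  rk <- sensitivity_ranking(net)
  expect_identical(rk$descriptor, c("a", "b", "c"))
  expect_equal(rk$ratio[rk$descriptor == "c"] > 1, TRUE)
  # a network that ignores an input ranks it last with ratio 1
  net0 <- net
  par <- qsrr:::.unpack(net0$weights, 3, 4)
  par$W1[, 3] <- 0
  net0$weights <- c(as.vector(par$W1), par$b1, par$W2, par$b2)
  rk0 <- sensitivity_ranking(net0)
  expect_identical(rk0$descriptor[3], "c")
  expect_equal(rk0$ratio[3], 1)
})
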