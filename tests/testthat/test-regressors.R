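test_that("linear fit recovers exact and noisy coefficients via QR", {
  set.seed(12)
  X <- matrix(stats::rnorm(200 * 5), 200, 5)
  beta <- c(2, -1, 0.5, 3, -0.25)
  m <- fit_linear(X, as.numeric(X %*% beta))
  expect_lt(max(abs(m$fit$beta[-1] - beta)), 1e-8)
  expect_lt(abs(m$fit$beta[1]), 1e-8)

  # constant target: intercept-only prediction
  mc <- fit_linear(X, rep(4.2, 200))
  expect_equal(predict(mc, X), rep(4.2, 200), tolerance = 1e-9)

  # normal-equations oracle on noisy data
  y <- as.numeric(X %*% beta) + stats::rnorm(200, 0, 0.1)
  m2 <- fit_linear(X, y)
  A <- cbind(1, X)
  beta_ne <- solve(t(A) %*% A, t(A) %*% y)
  expect_lt(max(abs(m2$fit$beta - beta_ne)), 1e-6)

  # rank-deficient design falls back with a warning
  Xd <- cbind(X, X[, 1])
  expect_warning(fit_linear(Xd, y), "rank-deficient")
})

test_that("ridge regression matches dense-inverse and least-squares
           oracles", {
  set.seed(13)
  X <- matrix(stats::rnorm(50 * 8), 50, 8)
  y <- as.numeric(X %*% stats::rnorm(8)) + stats::rnorm(50, 0, 0.05)

  # dual-form dense-inverse oracle at p >= n (forces the dual route)
  Xw <- matrix(stats::rnorm(30 * 40), 30, 40)
  yw <- stats::rnorm(30)
  mw <- fit_ridge(Xw, yw, alpha = 0.7)
  Xs <- scale(Xw)
  Xs[is.na(Xs)] <- 0
  K <- tcrossprod(Xs) + 0.7 * diag(30)
  a_ref <- solve(K, yw - mean(yw))
  expect_lt(max(abs(mw$fit$a - a_ref)), 1e-8)

  # primal route agrees with the dual formulation's predictions
  mp <- fit_ridge(X, y, alpha = 0.7)          # n > p: primal
  Xs2 <- scale(X)
  K2 <- tcrossprod(Xs2) + 0.7 * diag(50)
  a2 <- solve(K2, y - mean(y))
  pred_dual <- as.numeric(tcrossprod(Xs2) %*% a2) + mean(y)
  expect_lt(max(abs(predict(mp, X) - pred_dual)), 1e-8)

  # alpha -> 0 approaches the unregularised least-squares fit
  m0 <- fit_ridge(X, y, alpha = 1e-8)
  ml <- fit_linear(X, y)
  expect_lt(max(abs(predict(m0, X) - predict(ml, X))), 1e-4)

  # very large alpha shrinks predictions to the target mean
  mb <- fit_ridge(X, y, alpha = 1e9)
  expect_lt(max(abs(predict(mb, X) - mean(y))), 1e-3)

  expect_error(fit_ridge(X, y, alpha = 0), "positive")
})

test_that("kernel ridge interpolates smooth functions", {
  set.seed(14)
  x <- matrix(seq(-2, 2, length.out = 80), ncol = 1)
  y <- sin(2 * x[, 1])
  m <- fit_ridge(x, y, alpha = 1e-6, kernel = "gaussian", sigma = 0.5)
  xt <- matrix(seq(-1.9, 1.9, length.out = 50), ncol = 1)
  expect_lt(max(abs(predict(m, xt) - sin(2 * xt[, 1]))), 0.05)

  # 50-row dense-inverse oracle
  X <- matrix(stats::rnorm(50 * 4), 50, 4)
  yy <- stats::rnorm(50)
  mk <- fit_ridge(X, yy, alpha = 0.3, kernel = "gaussian", sigma = 2)
  Xs <- scale(X)
  D2 <- as.matrix(stats::dist(Xs))^2
  K <- exp(-D2 / (2 * 4)) + 0.3 * diag(50)
  expect_lt(max(abs(mk$fit$a - solve(K, yy - mean(yy)))), 1e-8)
})

test_that("epsilon-SVR fits within its tube and handles degenerate
           targets", {
  set.seed(15)
  x <- matrix(seq(0, 2 * pi, length.out = 100), ncol = 1)
  y <- sin(x[, 1])
  m <- fit_svr(x, y, C = 10, epsilon = 0.01, sigma = 0.5)
  # interpolation regime: training points reproduced within the tube plus
  # slack (epsilon is on the standardised scale: eps * sd(y))
  expect_lt(max(abs(predict(m, x) - y)), 0.05)
  xt <- matrix(stats::runif(60, 0.2, 2 * pi - 0.2), ncol = 1)
  expect_lt(sqrt(mean((predict(m, xt) - sin(xt[, 1]))^2)), 0.1)

  yc <- rep(3.3, 100)
  mc <- fit_svr(x, yc)
  expect_equal(predict(mc, x), rep(3.3, 100), tolerance = 1e-6)
})

test_that("the MLP trains deterministically to a linear target", {
  set.seed(16)
  x <- matrix(stats::runif(120, -1, 1), ncol = 1)
  y <- 2 * x[, 1]
  m <- fit_mlp(x, y, layers = c(8L, 4L), seed = 3, maxit = 400,
               lambda_wd = 0)
  expect_lt(mean((predict(m, x) - y)^2), 1e-3)

  m2 <- fit_mlp(x, y, layers = c(8L, 4L), seed = 3, maxit = 400,
                lambda_wd = 0)
  expect_identical(predict(m, x), predict(m2, x))

  # zero-iteration training still yields finite initialisation output
  m0 <- fit_mlp(x, y, layers = c(8L, 4L), seed = 3, maxit = 0)
  expect_true(all(is.finite(predict(m0, x))))
})

test_that("random forest averages trees and respects the target range", {
  set.seed(17)
  d <- toy_regression(n = 300, p = 6, seed = 2)
  m <- fit_random_forest(d$X, d$y, n_trees = 50, seed = 9)
  pr <- predict(m, d$X)
  expect_true(all(pr >= min(d$y) & pr <= max(d$y)))

  # single fully-grown tree is a lookup table at unique training points
  X1 <- matrix(seq_len(20), ncol = 1)
  y1 <- stats::rnorm(20)
  m1 <- fit_random_forest(X1, y1, n_trees = 1, min_leaf = 1, seed = 1)
  # bootstrap may exclude some points; check the in-bag ones match exactly
  hit <- predict(m1, X1) == y1
  expect_gt(mean(hit), 0.4)

  # separable two-cluster fixture: holdout error far below sd(y)
  Xc <- rbind(matrix(stats::rnorm(200, 0), ncol = 2),
              matrix(stats::rnorm(200, 6), ncol = 2))
  yc <- rep(c(1, 5), each = 100)
  ho <- c(1:20, 101:120)
  mc <- fit_random_forest(Xc[-ho, ], yc[-ho], seed = 4)
  expect_lt(sqrt(mean((predict(mc, Xc[ho, ]) - yc[ho])^2)), 0.2 * stats::sd(yc))
})

test_that("all families honour the shared fit/predict contract", {
  d <- toy_regression(n = 150, p = 8, seed = 5)
  Xte <- toy_regression(n = 40, p = 8, seed = 6)$X
  for (fam in regressor_families()) {
    m <- fit_regressor(fam, d$X, d$y, seed = 11)
    p1 <- predict(m, Xte)
    expect_length(p1, 40L)
    expect_true(all(is.finite(p1)), info = fam)

    # determinism under refit with the same seed
    m2 <- fit_regressor(fam, d$X, d$y, seed = 11)
    expect_equal(predict(m2, Xte), p1, info = fam)

    # serialisation round trip
    f <- tempfile(fileext = ".rds")
    saveRDS(m, f)
    expect_equal(predict(readRDS(f), Xte), p1, info = fam)
    unlink(f)

    # constant targets are reproduced (tree/linear exactly, others closely)
    mc <- fit_regressor(fam, d$X, rep(2.5, 150), seed = 11)
    expect_lt(max(abs(predict(mc, Xte) - 2.5)), 1e-4)

    # feature-width mismatch is a clear error
    expect_error(predict(m, Xte[, 1:5]), "width", info = fam)

    # empty input gives empty output
    expect_length(predict(m, Xte[0, , drop = FALSE]), 0L)
  }
})
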