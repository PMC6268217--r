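test_that("exact and null fits behave as closed forms dictate", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 + X %*% c(1, -2, 0.5)
  fit <- fit_mlr(X, drop(y))
  expect_equal(fit$r2, 1)
  expect_equal(fit$rmse, 0)
  expect_equal(unname(fit$coefficients), c(2, 1, -2, 0.5))
  expect_identical(fit$f_stat, Inf)

  # response orthogonal to all centered columns: slopes 0, intercept mean(y)
  y0 <- rnorm(10)
  y_orth <- residuals(lm(y0 ~ X)) + 5
  fit0 <- fit_mlr(X, y_orth)
  expect_equal(unname(fit0$coefficients[-1]), rep(0, 3), tolerance = 1e-10)
  expect_equal(fit0$intercept, mean(y_orth))
})

test_that("coefficients match an independent normal-equations solve", {
  set.seed(12)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("d", 1:3)))
  y <- rnorm(20)
  fit <- fit_mlr(X, y)
  expect_equal(unname(fit$coefficients), unname(oracle_coefs(X, y)),
               tolerance = 1e-8)
  # self-consistency of stored statistics
  expect_equal(fit$r2, r_squared(y, fit$fitted))
  expect_equal(fit$rmse, rmse(y, fit$fitted))
  # residuals orthogonal to every design column
  D <- cbind(1, X)
  expect_lt(max(abs(crossprod(D, fit$residuals))), 1e-8 * max(abs(y)) * 20)
})

test_that("degenerate designs fail loudly with named columns", {
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  X[, "d"] <- X[, "a"]
  expect_error(fit_mlr(X, rnorm(10)), "rank-deficient.*d")
  expect_error(fit_mlr(matrix(rnorm(6), 3, 2), rnorm(3)), "n > p \\+ 1")
})

test_that("r_squared and rmse match frozen hand computations", {
  y <- c(1, 2, 3, 4)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  # SSres = .01+.01+.04+.04 = 0.10; SStot = 5 -> 0.98
  expect_equal(r_squared(y, c(1.1, 1.9, 3.2, 3.8)), 0.98)
  expect_error(r_squared(rep(2, 4), y), "constant")

  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(c(1, 2), c(0, 3)), 1)          # residuals +1, -1
  expect_equal(rmse(rep(0, 5), 1:5), sqrt(11))      # sqrt(55/5)
})

test_that("F statistic agrees with the ANOVA decomposition and edge cases", {
  expect_equal(f_statistic(0, 20, 3), 0)
  expect_error(f_statistic(1, 20, 3), "infinite")
  set.seed(21)
  X <- matrix(rnorm(75), 25, 3)
  y <- drop(X %*% c(1, 0.5, -1)) + rnorm(25)
  fit <- fit_mlr(X, y)
  ssreg <- sum((fit$fitted - mean(y))^2)
  ssres <- sum(fit$residuals^2)
  f_anova <- (ssreg / 3) / (ssres / (25 - 3 - 1))
  expect_equal(f_statistic(fit$r2, 25, 3), f_anova, tolerance = 1e-8)
})

test_that("standardized coefficients are scale-invariant and match a z-score refit", {
  set.seed(8)
  X <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("u", "v")))
  y <- drop(X %*% c(2, -1)) + rnorm(15, 0, 0.5)
  fit <- fit_mlr(X, y)
  b_std <- standardized_coefficients(fit, X, y)

  # doubling a column halves its raw coefficient, leaves standardized one
  X2 <- X; X2[, "u"] <- 2 * X[, "u"]
  fit2 <- fit_mlr(X2, y)
  expect_equal(unname(fit2$coefficients["u"]), unname(fit$coefficients["u"]) / 2)
  expect_equal(standardized_coefficients(fit2, X2, y), b_std, tolerance = 1e-10)

  # refit on z-scored data reproduces them
  Xz <- scale(X); yz <- drop(scale(y))
  fitz <- fit_mlr(Xz, yz)
  # sd(y) uses n-1 on both sides, so ratios cancel exactly
  expect_equal(unname(fitz$coefficients[-1]), unname(b_std), tolerance = 1e-8)

  # pre-standardized input: standardized equal raw slopes
  fz <- fit_mlr(Xz, yz)
  expect_equal(standardized_coefficients(fz, Xz, yz),
               fz$coefficients[-1], tolerance = 1e-10)
})

test_that("external q2 uses the test-set mean and matches hand arithmetic", {
  y <- c(1, 2, 3, 4)
  expect_equal(external_q2(y, y), 1)
  expect_equal(external_q2(y, rep(mean(y), 4)), 0)
  # SSres = 1+0+1+4 = 6, SStot = 5 -> -0.2
  expect_equal(external_q2(y, c(2, 2, 2, 2)), -0.2)
  # training-mean variant differs when means differ
  expect_equal(external_q2_train_mean(y, c(2, 2, 2, 2), 0),
               1 - 6 / sum(y^2))
  expect_error(external_q2(rep(1, 3), c(1, 2, 3)), "constant")
})

test_that("training r2 never decreases when a column is added", {
  set.seed(33)
  for (rep in 1:5) {
    X <- matrix(rnorm(20 * 5), 20, 5)
    y <- rnorm(20)
    r2s <- vapply(1:5, function(p)
      fit_mlr(X[, 1:p, drop = FALSE], y)$r2, numeric(1))
    expect_true(all(diff(r2s) >= -1e-12))
  }
})
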