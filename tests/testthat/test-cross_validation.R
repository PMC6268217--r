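test_that("MCCV split plans are reproducible and correctly sized", {
  p1 <- make_mccv_splits(10, 0.5, N = 3, seed = 42)
  p2 <- make_mccv_splits(10, 0.5, N = 3, seed = 42)
  expect_identical(p1$validation, p2$validation)
  expect_true(all(vapply(p1$validation, length, 1L) == 5L))
  expect_true(all(vapply(p1$validation, function(v)
    length(unique(v)) == 5 && all(v %in% 1:10), TRUE)))

  # odd n, two-fold: construction gets the extra compound
  p53 <- make_mccv_splits(53, 0.5, N = 2, seed = 1)
  expect_identical(p53$n_v, 26L)

  expect_error(make_mccv_splits(3, 0.5, 10), ">= 4")
  expect_error(make_mccv_splits(10, 1.2, 10), "in \\(0, 1\\)")
})

test_that("validation membership frequency matches the sampling fraction", {
  n <- 10; N <- 4000
  plan <- make_mccv_splits(n, 0.5, N, seed = 7)
  freq <- tabulate(unlist(plan$validation), n) / N
  band <- 3 * sqrt(0.25 / N)
  expect_true(all(abs(freq - 0.5) < band))
})

test_that("LOOCV equals the explicit refit loop and detects overfitting", {
  sim <- make_signal_data(n = 30, m = 5, k = 3, noise = 0.3, seed = 2)
  X <- sim$train$X[, 1:4]; y <- sim$train$y
  loo <- loocv(X, y)
  press <- vapply(seq_along(y), function(i) {
    b <- oracle_coefs(X[-i, , drop = FALSE], y[-i])
    (y[i] - sum(c(1, X[i, ]) * b))^2
  }, 1)
  expect_equal(loo$q2_mean, 1 - sum(press) / sum((y - mean(y))^2),
               tolerance = 1e-10)
  expect_equal(loo$rmsev_mean, sqrt(mean(press)), tolerance = 1e-10)

  # perfect linear signal
  yl <- drop(X %*% c(1, 2, -1, 0.5)) + 3
  expect_equal(loocv(X, yl)$q2_mean, 1, tolerance = 1e-10)

  # pure noise: cross-validated q2 below the training r2
  set.seed(5)
  yn <- rnorm(30)
  expect_lt(loocv(X, yn)$q2_mean, fit_mlr(X, yn)$r2)
})

test_that("LMOCV summaries equal an independent re-implementation", {
  sim <- make_signal_data(n = 36, m = 6, k = 3, noise = 0.5, seed = 3)
  X <- sim$train$X[, 1:5]; y <- sim$train$y
  plan <- make_mccv_splits(36, 0.5, N = 50, seed = 13)
  got <- lmocv(X, y, plan)
  want <- oracle_lmocv(X, y, plan)
  expect_equal(got$q2_mean, want$q2_mean, tolerance = 1e-10)
  expect_equal(got$q2_std, want$q2_std, tolerance = 1e-10)
  expect_equal(got$rmsev_mean, want$rmsev_mean, tolerance = 1e-10)
  expect_equal(got$rmsev_std, want$rmsev_std, tolerance = 1e-10)
  expect_equal(got$per_split$q2, unname(want$q2), tolerance = 1e-10)
})

test_that("LMOCV degenerate plans behave as specified", {
  sim <- make_signal_data(n = 20, m = 4, k = 2, noise = 0.2, seed = 4)
  X <- sim$train$X[, 1:3]; y <- sim$train$y
  # N identical splits -> zero spread
  plan <- make_mccv_splits(20, 0.5, N = 4, seed = 9)
  plan$validation <- rep(plan$validation[1], 4)
  s <- lmocv(X, y, plan)
  expect_equal(s$q2_std, 0)
  expect_equal(s$rmsev_std, 0)

  # perfect signal: q2 = 1, rmsev = 0
  yl <- drop(X %*% c(1, -1, 2))
  plan2 <- make_mccv_splits(20, 0.5, N = 10, seed = 10)
  s2 <- lmocv(X, yl, plan2)
  expect_equal(s2$q2_mean, 1, tolerance = 1e-10)
  expect_equal(s2$rmsev_mean, 0, tolerance = 1e-6)
})

test_that("LMOCV with singleton validation sets reproduces pooled LOOCV", {
  sim <- make_signal_data(n = 18, m = 5, k = 3, noise = 0.4, seed = 6)
  X <- sim$train$X[, 1:4]; y <- sim$train$y
  plan <- make_mccv_splits(18, 0.5, N = 18, seed = 1)
  plan$validation <- as.list(1:18)
  plan$n_v <- 1L
  expect_message(s <- lmocv(X, y, plan), "pooling")
  loo <- loocv(X, y)
  expect_equal(s$q2_mean, loo$q2_mean, tolerance = 1e-10)
  expect_equal(s$rmsev_mean, loo$rmsev_mean, tolerance = 1e-10)
  expect_true(s$pooled)
})

test_that("mean q2 rises with signal-to-noise and never exceeds 1", {
  q2s <- vapply(c(2, 0.5, 0.1), function(noise) {
    sim <- make_signal_data(n = 40, m = 6, k = 3, noise = noise, seed = 17)
    plan <- make_mccv_splits(40, 0.5, N = 40, seed = 17)
    s <- lmocv(sim$train$X[, 1:3], sim$train$y, plan)
    expect_lte(s$q2_mean, 1)
    expect_gte(s$rmsev_mean, 0)
    s$q2_mean
  }, 1)
  expect_true(all(diff(q2s) > 0))
})
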