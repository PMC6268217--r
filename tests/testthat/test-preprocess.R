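make_table <- function(cols) {
  X <- do.call(cbind, cols)
  rownames(X) <- sprintf("c%02d", seq_len(nrow(X)))
  X
}

test_that("low-SD filter removes constants and respects the strict boundary", {
  set.seed(4)
  X <- make_table(list(v1 = rnorm(6), const = rep(1, 6), v2 = rnorm(6)))
  out <- filter_low_std(X)
  expect_identical(out$removed, "const")
  expect_identical(colnames(out$table), c("v1", "v2"))

  # a column whose SD equals the threshold exactly survives (strict "<")
  thr <- sd(X[, "v1"])
  out2 <- filter_low_std(X[, "v1", drop = FALSE], threshold = thr)
  expect_identical(out2$removed, character(0))
  out3 <- filter_low_std(X[, "v1", drop = FALSE], threshold = thr * (1 + 1e-12))
  expect_identical(out3$removed, "v1")

  expect_error(filter_low_std(X[1, , drop = FALSE]), ">= 2 compounds")
})

test_that("low-SD removals agree with per-column recomputation", {
  set.seed(9)
  X <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("c", 1:5), paste0("d", 1:4)))
  X[, 2] <- X[, 2] * 1e-7
  thr <- 1e-4
  out <- filter_low_std(X, thr)
  expect_identical(out$removed,
                   colnames(X)[apply(X, 2, sd) < thr])
})

test_that("correlation filter removes the later of each offending pair", {
  set.seed(2)
  base <- rnorm(12)
  X <- make_table(list(a = base, b = rnorm(12), a_dup = base, c = rnorm(12)))
  out <- filter_pairwise_correlation(X)
  expect_identical(out$removed$removed, "a_dup")
  expect_identical(out$removed$kept, "a")
  expect_equal(out$removed$abs_r, 1)
  expect_identical(colnames(out$table), c("a", "b", "c"))
})

test_that("a pair correlated just below the cutoff survives", {
  # construct exact sample correlation 0.94 via orthogonalization
  set.seed(7)
  n <- 20
  u <- scale(rnorm(n))[, 1]
  w <- residuals(lm(rnorm(n) ~ u))
  w <- scale(w)[, 1]
  X <- make_table(list(x1 = u, x2 = 0.94 * u + sqrt(1 - 0.94^2) * w))
  expect_equal(cor(X)[1, 2], 0.94, tolerance = 1e-12)
  out <- filter_pairwise_correlation(X, cutoff = 0.95)
  expect_identical(nrow(out$removed), 0L)
  out2 <- filter_pairwise_correlation(X, cutoff = 0.94 - 1e-9)
  expect_identical(out2$removed$removed, "x2")
})

test_that("greedy correlation scan matches an independent re-implementation", {
  set.seed(31)
  n <- 25
  base1 <- rnorm(n); base2 <- rnorm(n)
  X <- make_table(list(
    a1 = base1, a2 = base1 + rnorm(n, 0, 0.01), a3 = -base1 + rnorm(n, 0, 0.02),
    b1 = base2, b2 = base2 + rnorm(n, 0, 0.015),
    c1 = rnorm(n), c2 = rnorm(n), c3 = rnorm(n), c4 = rnorm(n), c5 = rnorm(n)))
  out <- filter_pairwise_correlation(X, cutoff = 0.95)
  expect_identical(colnames(out$table), oracle_correlation_filter(X, 0.95))
  expect_error(filter_pairwise_correlation(cbind(X, z = rep(2, n))),
               "zero-variance.*filter_low_std")
})

test_that("zero-inflation filter uses the >= 90% boundary", {
  X <- make_table(list(
    allzero = rep(0, 10),
    nine = c(rep(0, 9), 1),
    eight = c(rep(0, 8), 1, 2),
    dense = rnorm(10)))
  out <- filter_zero_inflated(X)
  expect_identical(sort(out$removed), c("allzero", "nine"))
  expect_identical(colnames(out$table), c("eight", "dense"))
})

test_that("pipeline buckets each pathology, conserves columns, is idempotent", {
  sim <- generate_qsar_dataset(n = 30, m = 8, true_indices = 1:2,
                               true_coefficients = c(1, -1), n_redundant = 1,
                               collinearity_rho = 0.995, n_constant = 1,
                               n_zero_inflated = 1, seed = 5)
  X <- sim$train$X
  out <- preprocess_descriptors(X)
  rep <- out$report
  expect_identical(rep$removed_by_std, "CONST01")
  expect_identical(rep$removed_by_correlation$removed, "RED01")
  expect_identical(rep$removed_by_zeros, "ZI01")
  # conservation: surviving + removed = original
  expect_identical(
    sort(c(rep$surviving, rep$removed_by_std,
           rep$removed_by_correlation$removed, rep$removed_by_zeros)),
    sort(rep$original))
  # the input table is untouched (removals recoverable)
  expect_identical(ncol(X), 11L)
  # idempotence / fixed point
  out2 <- preprocess_descriptors(out$table)
  expect_identical(out2$table, out$table)
  expect_identical(length(out2$report$removed_by_std), 0L)
  expect_identical(nrow(out2$report$removed_by_correlation), 0L)
  expect_identical(length(out2$report$removed_by_zeros), 0L)
})
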