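gates_off <- function(Ns = 10000, ...) {
  vsmvi_config(r_int = 1, r_cri = function(vn) -Inf, Ns = Ns, ...)
}

test_that("combination accounting is exact", {
  expect_identical(count_asr_combinations(10, 3), 120)
  expect_identical(count_asr_combinations(7, 7), 1)
  expect_identical(count_asr_combinations(5, 0), 1)
  expect_identical(count_asr_combinations(53, 5), 2869685)
  expect_error(count_asr_combinations(3, 5), "exceed")
  expect_identical(count_vsmvi_combinations(7, 1), 7)
  expect_identical(count_vsmvi_combinations(53, 1000), 53000)
})

test_that("exhaustive stage with m = vn keeps the single forced subset", {
  sim <- make_signal_data(n = 30, m = 10, seed = 5)
  d <- qsar_dataset(sim$train$X[, 1:3], sim$train$y)
  plan <- make_mccv_splits(30, 0.5, 20, seed = 3)
  pool <- exhaustive_stage(d, 3, gates_off(Na = 3), plan)
  expect_identical(nrow(pool$indices), 1L)
  expect_identical(unname(pool$indices[1, ]), 1:3)
})

test_that("the r_int gate keeps duplicate-correlated descriptors apart", {
  sim <- generate_qsar_dataset(n = 40, m = 8, true_indices = 1:2,
                               true_coefficients = c(1.5, -1), noise_sd = 0.3,
                               n_redundant = 1, collinearity_rho = 0.999,
                               seed = 8)
  d <- sim$train  # RED01 (column 9) nearly duplicates column 1
  stopifnot(abs(cor(d$X[, 1], d$X[, 9])) > 0.99)
  plan <- make_mccv_splits(40, 0.5, 20, seed = 2)
  cfg <- vsmvi_config(r_int = 0.9, r_cri = function(vn) -Inf, Ns = 1000)
  pool <- exhaustive_stage(d, 2, cfg, plan)
  both <- apply(pool$indices, 1, function(idx) all(c(1L, 9L) %in% idx))
  expect_false(any(both))
  # gate soundness across the whole pool
  cm <- abs(cor(d$X))
  viol <- apply(pool$indices, 1, function(idx) cm[idx[1], idx[2]] >= 0.9)
  expect_false(any(viol))
})

test_that("with gates off the pair pool equals a brute-force ranking", {
  sim <- make_signal_data(n = 35, m = 10, seed = 21)
  d <- sim$train
  plan <- make_mccv_splits(35, 0.5, 25, seed = 11)
  pool <- exhaustive_stage(d, 2, gates_off(), plan)
  expect_identical(nrow(pool$indices), 45L)

  combos <- combn(10, 2)
  sc <- vapply(seq_len(45), function(j)
    oracle_lmocv(d$X[, combos[, j]], d$y, plan)$q2_mean, 1)
  ord <- order(-sc)
  expect_equal(pool$sc, sc[ord], tolerance = 1e-10)
  expect_identical(pool$indices, t(combos[, ord]))
})

test_that("pool keeps exactly the top-Ns records under capacity pressure", {
  sim <- make_signal_data(n = 35, m = 10, seed = 22)
  d <- sim$train
  plan <- make_mccv_splits(35, 0.5, 25, seed = 12)
  small <- exhaustive_stage(d, 2, gates_off(Ns = 7), plan)
  full <- exhaustive_stage(d, 2, gates_off(), plan)
  expect_identical(nrow(small$indices), 7L)
  expect_identical(small$indices, full$indices[1:7, ])
  expect_equal(small$sc, full$sc[1:7])
  # enlarging Ns never lowers the best score
  expect_gte(full$sc[1], small$sc[1])
})

test_that("extension stage deduplicates children reachable from two parents", {
  sim <- make_signal_data(n = 30, m = 6, seed = 23)
  d <- sim$train
  plan <- make_mccv_splits(30, 0.5, 15, seed = 13)
  parents <- exhaustive_stage(d, 2, gates_off(), plan)  # all 15 pairs
  child <- extension_stage(d, parents, gates_off(), plan)
  keys <- apply(child$indices, 1, paste, collapse = ",")
  expect_identical(anyDuplicated(keys), 0L)
  expect_identical(nrow(child$indices), 20L)  # C(6,3)
  counts <- child$counts
  expect_lte(counts[["generated"]], count_vsmvi_combinations(6, nrow(parents$indices)))
  # single-parent counting: at most m - (vn-1) children evaluated
  one <- parents
  one$indices <- parents$indices[1, , drop = FALSE]
  one$sc <- parents$sc[1]; one$r2 <- parents$r2[1]; one$names <- parents$names[1]
  ext1 <- extension_stage(d, one, gates_off(), plan)
  expect_identical(unname(ext1$counts[["generated"]]), 4)
})

test_that("search equals exhaustive all-subsets scan when the pool is unbounded", {
  sim <- make_signal_data(n = 40, m = 12, k = 3, noise = 0.4, seed = 31)
  d <- sim$train
  cfg <- vsmvi_config(vm = 4, Ns = 10000, Na = 3, cv_N = 30, seed = 77)
  res <- run_vsmvi(d, cfg)
  plan <- res$plan
  for (k in 2:4) {
    want <- oracle_best_subset(d$X, d$y, k, plan,
                               r_int = 0.9, r_cri = cfg$r_cri(k))
    got <- best_subset(res, k)
    expect_identical(unname(got$indices), want$idx)
    expect_equal(got$sc, want$sc, tolerance = 1e-8)
  }
})

test_that("run_vsmvi at size 1 ranks singletons by training correlation", {
  sim <- make_signal_data(n = 30, m = 8, seed = 41)
  d <- sim$train
  res <- run_vsmvi(d, gates_off(vm = 1, cv_N = 20, seed = 5))
  pool <- res$pools[[1]]
  expect_identical(nrow(pool$indices), 8L)
  # training r2 of a singleton is its squared correlation with y
  r2s <- drop(cor(d$X, d$y))^2
  expect_equal(pool$r2, unname(r2s[pool$indices[, 1]]), tolerance = 1e-10)
})

test_that("trace accounting is complete and within the extension bound", {
  sim <- make_signal_data(n = 60, m = 20, k = 3, noise = 0.4, seed = 51)
  res <- run_vsmvi(sim$train, vsmvi_config(vm = 4, Ns = 50, cv_N = 20, seed = 6))
  tr <- res$trace
  expect_identical(tr$size, 1:4)
  # generated = gated + scored (+failed/duplicates)
  expect_equal(tr$generated,
               tr$gated_rint + tr$gated_rcri + tr$scored + tr$failed + tr$duplicates)
  expect_identical(tr$generated[1:3], choose(20, 1:3))
  expect_lte(tr$generated[4], count_vsmvi_combinations(20, 50))
  # no pool record violates its gates
  cm <- abs(cor(sim$train$X))
  for (p in res$pools) {
    if (p$size >= 2) {
      viol <- apply(p$indices, 1, function(idx)
        max(cm[idx, idx][upper.tri(diag(length(idx)))]) >= 0.9)
      expect_false(any(viol))
    }
    expect_true(all(p$r2 >= p$r_cri))
  }
})

test_that("model-size selection implements the <5% gain rule", {
  expect_identical(select_model_size(c(0.30, 0.55, 0.62, 0.630, 0.634)), 3L)
  expect_identical(select_model_size(rep(0.5, 4)), 1L)
  expect_identical(select_model_size(c(0.1, 0.2, 0.4, 0.8)), 4L)
  expect_identical(select_model_size(c(0.5, 0.4)), 1L)  # loss stops immediately
  expect_error(select_model_size(0.5), "at least 2")
})

test_that("the planted four-descriptor subset is recovered (spot check)", {
  sim <- generate_qsar_dataset(n = 60, m = 40, seed = 123)
  res <- run_vsmvi(sim$train, vsmvi_config(vm = 4, seed = 123))
  expect_identical(sort(unname(best_subset(res, 4)$indices)),
                   sim$truth$true_indices)
})
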