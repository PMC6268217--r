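# Chance-correlation testing: y-randomization runs and the c r2p
# distance-from-chance statistic.

#' y-randomization (response scrambling) validation
#'
#' Permutes the response uniformly `runs` times; for each permutation the
#' MLR model on the *fixed* descriptor subset is refitted and its training
#' r2 and mean LMOCV q2 (on the same split plan as the real model, so the
#' comparison is like-for-like) are recorded. A real relationship should
#' give much higher r2 and q2 than the scrambled runs; scrambled q2 values
#' are typically below zero.
#'
#' The subset is *not* re-selected per permutation by default, so this is a
#' model-level test; re-running the full search under each permutation
#' (a selection-level test, far more expensive) is available via
#' `reselect = TRUE`.
#'
#' @param X Descriptor matrix restricted to the model subset.
#' @param y Response vector.
#' @param runs Number of random permutations (default 1000).
#' @param plan `split_plan` used for the real model's LMOCV.
#' @param seed Optional integer seed; the whole summary is reproducible
#'   from it.
#' @param reselect If `TRUE`, rerun the VSMVI search on each permuted
#'   response and record the best model found (requires `config`).
#' @param config `vsmvi_config` for `reselect = TRUE`.
#' @return An object of class `randomization_summary`: per-run `r2_values`
#'   and `q2_values`, their means, `runs` and `seed`.
#' @export
y_randomization <- function(X, y, runs = 1000, plan, seed = NULL,
                            reselect = FALSE, config = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  runs <- check_count(runs, "runs")
  stopifnot(inherits(plan, "split_plan"))
  n <- nrow(X)
  if (length(y) != n) stop_data("length(y) must equal nrow(X)")
  fit_mlr(X, y)  # fail early (singular design) before the permutation loop
  perms <- with_seed(seed, replicate(runs, sample.int(n), simplify = FALSE))
  subset <- matrix(seq_len(ncol(X)), nrow = 1)
  r2s <- q2s <- numeric(runs)
  for (i in seq_len(runs)) {
    yp <- y[perms[[i]]]
    if (reselect) {
      res <- run_vsmvi(qsar_dataset(X, yp), config)
      top <- best_subset(res)
      r2s[i] <- top$r2; q2s[i] <- top$sc
    } else {
      sc <- cpp_score_subsets(X, yp, subset, plan$validation)
      r2s[i] <- sc$r2[1]; q2s[i] <- sc$q2_mean[1]
    }
  }
  structure(list(runs = runs, r2_values = r2s, q2_values = q2s,
                 r2_mean = mean(r2s), q2_mean = mean(q2s),
                 seed = seed, reselect = reselect),
            class = "randomization_summary")
}

#' @export
print.randomization_summary <- function(x, ...) {
  cat(sprintf("<randomization_summary> %d runs%s\n", x$runs,
              if (x$reselect) " (selection re-run per permutation)" else ""))
  cat(sprintf("  mean r2 of random models : %.4f\n", x$r2_mean))
  cat(sprintf("  mean q2 of random models : %.4f (%.1f%% below zero)\n",
              x$q2_mean, 100 * mean(x$q2_values < 0)))
  invisible(x)
}

#' Distance of a model from chance correlation (c r2p)
#'
#' Roy's penalized statistic `r * sqrt(r2 - r2_rand_mean)` with
#' `r = sqrt(r2)`: the model's correlation discounted by how much of it a
#' random-response model achieves on average. Values close to `r2` mean
#' the model is far from chance; a mean random r2 exceeding the model's r2
#' (model indistinguishable from chance) is an error, not silently clipped.
#'
#' @param r2 Training r2 of the real model.
#' @param r2_rand_mean Mean training r2 over the y-randomization runs.
#' @return The c r2p value.
#' @export
crp_statistic <- function(r2, r2_rand_mean) {
  if (!is.finite(r2) || r2 < 0 || r2 > 1) stop_data("r2 must be in [0, 1]")
  if (!is.finite(r2_rand_mean) || r2_rand_mean < 0)
    stop_data("r2_rand_mean must be non-negative")
  if (r2_rand_mean > r2)
    stop_numeric("mean randomized r2 (", signif(r2_rand_mean, 4),
                 ") exceeds the model r2 (", signif(r2, 4),
                 "): model indistinguishable from chance")
  sqrt(r2) * sqrt(r2 - r2_rand_mean)
}
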