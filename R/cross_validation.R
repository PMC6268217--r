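# Leave-one-out and leave-multiple-out Monte-Carlo cross-validation with
# per-split q2 / RMSEV and their means and standard deviations over splits.

#' Build a Monte-Carlo cross-validation split plan
#'
#' Draws `N` random construction/validation partitions of `n` compounds.
#' Each validation set contains `floor(fraction * n)` compounds sampled
#' uniformly without replacement (for two-fold splits of odd `n` the
#' construction set gets the extra compound, keeping fits well-posed).
#'
#' One plan is meant to be shared across every candidate subset of a search
#' run: paired comparison on identical splits removes Monte-Carlo noise
#' from the subset ranking.
#'
#' @param n Number of compounds (`n >= 4`).
#' @param fraction Validation share in (0, 1); default 0.5 (two-fold).
#' @param N Number of random splits.
#' @param seed Optional integer seed; the plan is reproducible from it and
#'   the caller's RNG stream is left untouched.
#' @return An object of class `split_plan`: list of validation index
#'   vectors plus `n`, `n_v`, `N`, `fraction`, `seed`.
#' @export
make_mccv_splits <- function(n, fraction = 0.5, N = 100, seed = NULL) {
  n <- check_count(n, "n", min = 4)
  N <- check_count(N, "N", min = 1)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop_data("fraction must be in (0, 1)")
  n_v <- max(1L, as.integer(floor(fraction * n)))
  if (n - n_v < 2) stop_data("validation share leaves fewer than 2 construction compounds")
  validation <- with_seed(seed,
    replicate(N, sort(sample.int(n, n_v)), simplify = FALSE))
  structure(list(validation = validation, n = n, n_v = n_v, N = N,
                 fraction = fraction, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> N = %d splits, n = %d (construction %d / validation %d)\n",
              x$N, x$n, x$n - x$n_v, x$n_v))
  invisible(x)
}

new_cv_summary <- function(method, q2_mean, rmsev_mean, q2_std, rmsev_std,
                           per_split = NULL, pooled = FALSE, extra = list()) {
  structure(c(list(method = method, q2_mean = q2_mean, rmsev_mean = rmsev_mean,
                   q2_std = q2_std, rmsev_std = rmsev_std,
                   per_split = per_split, pooled = pooled), extra),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("<cv_summary> %s%s\n", x$method, if (x$pooled) " (pooled residuals)" else ""))
  cat(sprintf("  q2    = %.4f (STD %s)\n", x$q2_mean,
              if (is.na(x$q2_std)) "n/a" else sprintf("%.4f", x$q2_std)))
  cat(sprintf("  RMSEV = %.4f (STD %s)\n", x$rmsev_mean,
              if (is.na(x$rmsev_std)) "n/a" else sprintf("%.4f", x$rmsev_std)))
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' LOOCV via the hat-matrix closed form: the predicted residual of
#' compound i equals `e_i / (1 - h_ii)`, so no refitting loop is needed.
#' Because single-compound validation sets have no per-split q2, LOOCV
#' pools the predicted residuals: `q2 = 1 - PRESS/SStot` and
#' `RMSEV = sqrt(PRESS/n)`.
#'
#' @param X Descriptor matrix (n x p, `n > p + 2`).
#' @param y Response vector.
#' @return A `cv_summary` with pooled `q2_mean`/`rmsev_mean` (`*_std` are
#'   `NA`: there are no per-split statistics to vary), plus the vector of
#'   predicted (PRESS) residuals.
#' @export
loocv <- function(X, y) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 2) stop_data("need n > p + 2 for LOOCV")
  D <- cbind(1, X)
  qrd <- qr(D)
  if (qrd$rank < ncol(D)) stop_numeric("singular training design")
  b <- qr.coef(qrd, y)
  resid <- y - drop(D %*% b)
  h <- rowSums(qr.Q(qrd)^2)
  bad <- which(h >= 1 - 1e-8)
  if (length(bad))
    stop_numeric("singular training design when leaving out compound ",
                 bad[1], " (leverage 1)")
  press_resid <- resid / (1 - h)
  press <- sum(press_resid^2)
  sstot <- sum((y - mean(y))^2)
  new_cv_summary("loocv", q2_mean = 1 - press / sstot,
                 rmsev_mean = sqrt(press / n), q2_std = NA_real_,
                 rmsev_std = NA_real_, pooled = TRUE,
                 extra = list(press = press, predicted_residuals = press_resid))
}

#' Leave-multiple-out Monte-Carlo cross-validation
#'
#' For each split of the plan: fit on the construction set, predict the
#' validation set, and record `q2_i` (1 - SSres/SStot about the
#' validation-set mean) and `rmsev_i`. Reports the means and standard
#' deviations of both across the N splits.
#'
#' Splits whose construction design is singular are reported as failed;
#' more than 10% failed splits is an error. If the plan's validation sets
#' are singletons (LOOCV expressed as LMOCV), per-split q2 is undefined and
#' the summary pools predicted residuals instead, exactly as [loocv()]
#' does; a message announces the switch.
#'
#' @param X Descriptor matrix.
#' @param y Response vector.
#' @param plan A `split_plan` from [make_mccv_splits()].
#' @return A `cv_summary`; `per_split` holds the per-split statistics.
#' @export
lmocv <- function(X, y, plan) {
  stopifnot(inherits(plan, "split_plan"))
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n != plan$n) stop_data("plan was built for n = ", plan$n, ", data has n = ", n)
  pooled <- plan$n_v < 2
  if (pooled)
    message("singleton validation sets: per-split q2 undefined, pooling predicted residuals")
  q2s <- rmsevs <- rep(NA_real_, plan$N)
  failed <- logical(plan$N)
  pooled_obs <- pooled_pred <- list()
  for (s in seq_len(plan$N)) {
    val <- plan$validation[[s]]
    cons <- setdiff(seq_len(n), val)
    if (length(cons) <= p + 1) {
      failed[s] <- TRUE
      next
    }
    D <- cbind(1, X[cons, , drop = FALSE])
    fit <- lm.fit(D, y[cons])
    if (fit$rank < ncol(D)) {
      failed[s] <- TRUE
      next
    }
    pred <- drop(cbind(1, X[val, , drop = FALSE]) %*% fit$coefficients)
    yv <- y[val]
    rmsevs[s] <- rmse(yv, pred)
    if (!pooled) q2s[s] <- external_q2(yv, pred)
    pooled_obs[[s]] <- yv
    pooled_pred[[s]] <- pred
  }
  if (mean(failed) > 0.10)
    stop_numeric(sum(failed), " of ", plan$N, " folds had singular designs")
  per_split <- data.frame(q2 = q2s, rmsev = rmsevs, failed = failed)
  ok <- !failed
  if (pooled) {
    obs <- unlist(pooled_obs); prd <- unlist(pooled_pred)
    press <- sum((obs - prd)^2)
    sstot <- sum((obs - mean(obs))^2)
    new_cv_summary("lmocv", q2_mean = 1 - press / sstot,
                   rmsev_mean = sqrt(press / length(obs)),
                   q2_std = NA_real_, rmsev_std = NA_real_,
                   per_split = per_split, pooled = TRUE,
                   extra = list(press = press))
  } else {
    new_cv_summary("lmocv",
                   q2_mean = mean(q2s[ok]), rmsev_mean = mean(rmsevs[ok]),
                   q2_std = if (sum(ok) > 1) stats::sd(q2s[ok]) else NA_real_,
                   rmsev_std = if (sum(ok) > 1) stats::sd(rmsevs[ok]) else NA_real_,
                   per_split = per_split)
  }
}
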