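# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: plain normal equations / qr fits and
# explicit loops, so agreement is a genuine dual-route check.

# OLS coefficients by directly solving the normal equations.
oracle_coefs <- function(X, y) {
  D <- cbind(1, as.matrix(X))
  solve(crossprod(D), crossprod(D, y))[, 1]
}

oracle_r2 <- function(y, y_hat) 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)

# Explicit LMOCV loop: fit on construction rows, predict validation rows,
# per-split q2 about the validation mean, RMSEV with denominator n_v.
oracle_lmocv <- function(X, y, plan) {
  X <- as.matrix(X)
  stats <- vapply(plan$validation, function(val) {
    cons <- setdiff(seq_along(y), val)
    b <- oracle_coefs(X[cons, , drop = FALSE], y[cons])
    pred <- drop(cbind(1, X[val, , drop = FALSE]) %*% b)
    ssres <- sum((y[val] - pred)^2)
    c(q2 = 1 - ssres / sum((y[val] - mean(y[val]))^2),
      rmsev = sqrt(ssres / length(val)))
  }, c(q2 = 0, rmsev = 0))
  list(q2 = stats["q2", ], rmsev = stats["rmsev", ],
       q2_mean = mean(stats["q2", ]), q2_std = sd(stats["q2", ]),
       rmsev_mean = mean(stats["rmsev", ]), rmsev_std = sd(stats["rmsev", ]))
}

# Brute-force all-subsets scan at one size with the search's gates:
# every size-k combination, skip if any pairwise |r| >= r_int or training
# r2 < r_cri, score by mean LMOCV q2, return the best (ties: smaller
# index set lexicographically).
oracle_best_subset <- function(X, y, k, plan, r_int = Inf, r_cri = -Inf) {
  X <- as.matrix(X)
  cmat <- abs(cor(X))
  combos <- utils::combn(ncol(X), k)
  best <- NULL
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    if (k > 1 && max(cmat[idx, idx][upper.tri(diag(k))]) >= r_int) next
    b <- oracle_coefs(X[, idx, drop = FALSE], y)
    r2 <- oracle_r2(y, drop(cbind(1, X[, idx, drop = FALSE]) %*% b))
    if (r2 < r_cri) next
    sc <- oracle_lmocv(X[, idx, drop = FALSE], y, plan)$q2_mean
    if (is.null(best) || sc > best$sc ||
        (sc == best$sc && paste(idx, collapse = ",") <
           paste(best$idx, collapse = ","))) {
      best <- list(idx = idx, sc = sc, r2 = r2)
    }
  }
  best
}

# Greedy pairwise-correlation filter, re-implemented independently.
oracle_correlation_filter <- function(X, cutoff) {
  cm <- abs(cor(X))
  alive <- seq_len(ncol(X))
  j <- 1
  while (j < length(alive)) {
    drop <- alive[-seq_len(j)][cm[alive[j], alive[-seq_len(j)]] >= cutoff]
    alive <- setdiff(alive, drop)
    j <- j + 1
  }
  colnames(X)[alive]
}

# Small standard fixture used across tests.
make_signal_data <- function(n = 40, m = 10, k = 3, noise = 0.4, seed = 1) {
  generate_qsar_dataset(n = n, m = m, true_indices = seq_len(k),
                        true_coefficients = c(1.2, -1.0, 0.8)[seq_len(k)],
                        noise_sd = noise, seed = seed)
}
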