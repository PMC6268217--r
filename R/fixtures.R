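# Deterministic synthetic QSAR fixtures: descriptor tables with a sparse
# linear signal, optional correlated/redundant, near-constant and
# zero-inflated columns, and ground truth carried alongside the data.
# Decoy descriptors and response noise are Gaussian -- the simplest law
# under which OLS recovery is well understood and adequate for exercising
# the machinery; no attempt is made to mimic real Dragon descriptor
# marginals.

#' Generate a synthetic QSAR dataset with known ground truth
#'
#' The response follows `y = intercept + sum(b_j x_j) + N(0, noise_sd)`
#' over `|true_indices|` planted signal columns; the remaining descriptors
#' are independent Gaussian decoys. Optional pathological columns are
#' appended after the `m` base descriptors: redundant columns correlated at
#' `collinearity_rho` with planted ones, exactly constant columns, and
#' zero-inflated columns -- one of each kind per count requested, so the
#' preselection filters have known targets. An external test set, when
#' requested, is drawn from the same law.
#'
#' @param n Number of training compounds (`n > |true_indices| + 2`).
#' @param m Number of base descriptors.
#' @param true_indices Positions (within `1..m`) of the signal columns.
#' @param true_coefficients Their coefficients (same length).
#' @param intercept Response intercept (default 0).
#' @param noise_sd Gaussian response-noise SD (default 0.3).
#' @param n_redundant Number of appended columns correlated with planted
#'   ones at `collinearity_rho` (cycled over the planted columns).
#' @param collinearity_rho Correlation of redundant columns (default 0.98).
#' @param n_constant,n_zero_inflated Counts of appended pathological
#'   columns; zero-inflated columns have `zero_fraction` exact zeros.
#' @param zero_fraction Zero share of zero-inflated columns (default 0.95).
#' @param n_test External test-set size (0 = none).
#' @param seed Integer seed; output is fully determined by it.
#' @return A list with `train` (a `qsar_dataset`), `test` (`qsar_dataset`
#'   or `NULL`) and `truth` (planted positions, names, coefficients,
#'   intercept, noise SD, seed).
#' @export
generate_qsar_dataset <- function(n = 60, m = 40, true_indices = 1:4,
                                  true_coefficients = c(1.5, -1.2, 1.0, 0.8),
                                  intercept = 0, noise_sd = 0.3,
                                  n_redundant = 0, collinearity_rho = 0.98,
                                  n_constant = 0, n_zero_inflated = 0,
                                  zero_fraction = 0.95, n_test = 0,
                                  seed = NULL) {
  n <- check_count(n, "n"); m <- check_count(m, "m")
  if (length(true_indices) != length(true_coefficients))
    stop_data("true_indices and true_coefficients must have equal length")
  if (any(true_indices < 1 | true_indices > m))
    stop_data("true_indices must lie in 1..m")
  if (n <= length(true_indices) + 2)
    stop_data("need n > |true_indices| + 2")
  if (collinearity_rho < 0 || collinearity_rho >= 1)
    stop_data("collinearity_rho must be in [0, 1)")
  if (noise_sd < 0) stop_data("noise_sd must be non-negative")

  with_seed(seed, {
    draw <- function(nrow, prefix) {
      X <- matrix(stats::rnorm(nrow * m), nrow, m,
                  dimnames = list(sprintf("%s%03d", prefix, seq_len(nrow)),
                                  sprintf("D%03d", seq_len(m))))
      cols <- list(X)
      if (n_redundant > 0) {
        red <- vapply(seq_len(n_redundant), function(i) {
          base <- true_indices[(i - 1) %% length(true_indices) + 1]
          collinearity_rho * X[, base] +
            sqrt(1 - collinearity_rho^2) * stats::rnorm(nrow)
        }, numeric(nrow))
        colnames(red) <- sprintf("RED%02d", seq_len(n_redundant))
        cols <- c(cols, list(red))
      }
      if (n_constant > 0) {
        cst <- matrix(1, nrow, n_constant,
                      dimnames = list(NULL, sprintf("CONST%02d", seq_len(n_constant))))
        cols <- c(cols, list(cst))
      }
      if (n_zero_inflated > 0) {
        zi <- vapply(seq_len(n_zero_inflated), function(i) {
          v <- stats::rnorm(nrow)
          v[sample.int(nrow, round(zero_fraction * nrow))] <- 0
          v
        }, numeric(nrow))
        colnames(zi) <- sprintf("ZI%02d", seq_len(n_zero_inflated))
        cols <- c(cols, list(zi))
      }
      full <- do.call(cbind, cols)
      rownames(full) <- sprintf("%s%03d", prefix, seq_len(nrow))
      y <- intercept + drop(X[, true_indices, drop = FALSE] %*% true_coefficients) +
        stats::rnorm(nrow, 0, noise_sd)
      qsar_dataset(full, y)
    }
    train <- draw(n, "C")
    test <- if (n_test > 0) draw(n_test, "T") else NULL
    truth <- list(true_indices = true_indices,
                  true_names = colnames(train$X)[true_indices],
                  true_coefficients = true_coefficients,
                  intercept = intercept, noise_sd = noise_sd, seed = seed)
    list(train = train, test = test, truth = truth)
  })
}

#' Fixture shaped like a small estrogen-receptor QSAR study
#'
#' A training set of 53 compounds with a 16-compound external test set and
#' `m` descriptors (default 120, a width chosen for test speed), with five
#' planted signal columns whose coefficient pattern echoes a published
#' five-descriptor estrogen-binding model (four negative terms, one
#' dominant positive), plus redundant, constant and zero-inflated columns
#' for the preselection filters to find.
#'
#' @param seed Integer seed.
#' @param m Number of base descriptors (pathological columns are appended).
#' @param noise_sd Response-noise SD (default 0.3).
#' @return As [generate_qsar_dataset()].
#' @export
paper_shaped_fixture <- function(seed = 1, m = 110, noise_sd = 0.3) {
  generate_qsar_dataset(
    n = 53, m = m, true_indices = 1:5,
    true_coefficients = c(-0.63, -0.52, -0.37, -0.58, 0.79),
    noise_sd = noise_sd, n_redundant = 6, collinearity_rho = 0.98,
    n_constant = 2, n_zero_inflated = 2, n_test = 16, seed = seed)
}
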