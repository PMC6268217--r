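# Ordinary least squares on a descriptor subset, with the fit and
# external-prediction statistics used throughout the toolkit.

#' Fit a multiple linear regression model on a descriptor subset
#'
#' Ordinary least squares of `y` on the columns of `X` plus an intercept.
#' Fails loudly on rank-deficient or numerically near-singular designs
#' (reciprocal condition of the triangular factor below 1e-10), naming the
#' offending columns, rather than returning unstable coefficients --
#' descriptor tables are near-collinear by nature.
#'
#' @param X Numeric matrix, n compounds x p descriptors (p >= 1), with
#'   column names.
#' @param y Numeric response of length n; requires `n > p + 1`.
#' @return An object of class `mlr_model`: coefficients (intercept first),
#'   fitted values, residuals, `r2`, `rmse` (denominator n), `f_stat`, `n`,
#'   `p`, and the descriptor `subset` (column names).
#' @export
fit_mlr <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_data("length(y) must equal nrow(X)")
  if (!all(is.finite(X)) || !all(is.finite(y))) stop_data("X and y must be finite")
  if (n <= p + 1)
    stop_numeric(sprintf("need n > p + 1 (n = %d, p = %d)", n, p))
  D <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(D)
  if (qrd$rank < ncol(D)) {
    off <- colnames(D)[qrd$pivot[seq(qrd$rank + 1, ncol(D))]]
    stop_numeric("rank-deficient design; offending column(s): ",
                 paste(off, collapse = ", "))
  }
  dR <- abs(diag(qr.R(qrd)))
  if (min(dR) / max(dR) < 1e-10) {
    off <- colnames(D)[qrd$pivot[which.min(dR)]]
    stop_numeric("near-singular design (condition beyond tolerance); ",
                 "offending column: ", off)
  }
  b <- qr.coef(qrd, y)
  fitted <- drop(D %*% b)
  resid <- y - fitted
  r2 <- r_squared(y, fitted)
  mod_rmse <- rmse(y, fitted)
  f <- if (r2 < 1) f_statistic(r2, n, p) else Inf
  structure(list(subset = colnames(X), coefficients = b,
                 intercept = unname(b[1]), fitted = fitted, residuals = resid,
                 r2 = r2, rmse = mod_rmse, f_stat = f, n = n, p = p),
            class = "mlr_model")
}

#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf("<mlr_model> %d descriptors, n = %d\n", x$p, x$n))
  cat(sprintf("  r2 = %.4f  RMSE = %.4f  F = %.4f\n", x$r2, x$rmse, x$f_stat))
  cat("  terms:", paste(x$subset, collapse = ", "), "\n")
  invisible(x)
}

#' Predict from a fitted MLR model
#'
#' Applies the model verbatim to new compounds (no re-centering to the new
#' set). Descriptor columns are matched by name.
#'
#' @param object An `mlr_model`.
#' @param newdata Numeric matrix containing at least the model's descriptor
#'   columns.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$subset, colnames(newdata))
  if (length(missing))
    stop_data("descriptor column(s) missing from new data: ",
              paste(missing, collapse = ", "))
  D <- cbind(1, newdata[, object$subset, drop = FALSE])
  drop(D %*% object$coefficients)
}

#' Coefficient of determination
#'
#' `1 - SSres/SStot` with the total sum of squares taken about `mean(y)`.
#'
#' @param y Observed values (non-constant, length >= 2).
#' @param y_hat Fitted/predicted values, same length.
#' @return A number `<= 1` (negative when `y_hat` is worse than the mean).
#' @export
r_squared <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) < 2)
    stop_data("y and y_hat must have equal length >= 2")
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) stop_numeric("r_squared undefined for constant y")
  1 - sum((y - y_hat)^2) / sstot
}

#' Root-mean-square error
#'
#' `sqrt(mean((y - y_hat)^2))` -- the denominator is n, not a residual
#' degree of freedom, so values are comparable across fold sizes in
#' cross-validation.
#'
#' @param y,y_hat Equal-length numeric vectors.
#' @return A non-negative number.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) < 1)
    stop_data("y and y_hat must have equal length >= 1")
  sqrt(mean((y - y_hat)^2))
}

#' F statistic of an MLR fit from its r-squared
#'
#' `(r2/p) / ((1 - r2)/(n - p - 1))`, the ratio of explained to residual
#' mean squares.
#'
#' @param r2 Training coefficient of determination in `[0, 1)`.
#' @param n Number of compounds (`n > p + 1`).
#' @param p Number of descriptors.
#' @return The F statistic.
#' @export
f_statistic <- function(r2, n, p) {
  n <- check_count(n, "n"); p <- check_count(p, "p")
  if (!is.finite(r2) || r2 < 0) stop_data("r2 must be in [0, 1)")
  if (r2 >= 1) stop_numeric("F statistic is infinite at r2 = 1")
  if (n <= p + 1) stop_data("need n > p + 1")
  (r2 / p) / ((1 - r2) / (n - p - 1))
}

#' Standardized regression coefficients
#'
#' `b_j * sd(x_j) / sd(y)` for each descriptor; the intercept has no
#' standardized form and is omitted. Standardized coefficients are
#' scale-invariant and rank descriptor importance on a common footing.
#'
#' @param model A fitted `mlr_model`.
#' @param X The training descriptor matrix (containing the model columns).
#' @param y The training response.
#' @return Named numeric vector, one value per model descriptor.
#' @export
standardized_coefficients <- function(model, X, y) {
  stopifnot(inherits(model, "mlr_model"))
  X <- as.matrix(X)[, model$subset, drop = FALSE]
  sx <- apply(X, 2, stats::sd)
  if (any(sx == 0))
    stop_numeric("zero-variance column(s): ",
                 paste(colnames(X)[sx == 0], collapse = ", "))
  sy <- stats::sd(y)
  if (sy == 0) stop_numeric("zero-variance response")
  model$coefficients[-1] * sx / sy
}

#' External predictive q-squared
#'
#' `1 - sum((y_i - yhat_i)^2) / sum((y_i - ybar_test)^2)` over an external
#' test set, with the reference mean taken from the test set itself. May be
#' negative when predictions are worse than the test-set mean.
#'
#' @param y_test Observed external responses (non-constant, length >= 2).
#' @param y_pred Model predictions for the same compounds.
#' @return The external q2.
#' @seealso [external_q2_train_mean()] for the training-mean variant.
#' @export
external_q2 <- function(y_test, y_pred) {
  if (length(y_test) != length(y_pred) || length(y_test) < 2)
    stop_data("y_test and y_pred must have equal length >= 2")
  sstot <- sum((y_test - mean(y_test))^2)
  if (sstot == 0) stop_numeric("external_q2 undefined for constant y_test")
  1 - sum((y_test - y_pred)^2) / sstot
}

#' External q-squared referenced to the training-set mean
#'
#' Variant of [external_q2()] whose denominator sums squared deviations of
#' the test responses from the training-set mean. Provided for comparison;
#' the test-set-mean form is the default elsewhere in the package.
#'
#' @param y_test,y_pred As in [external_q2()].
#' @param y_train_mean Mean response of the training set.
#' @return The q2 value.
#' @export
external_q2_train_mean <- function(y_test, y_pred, y_train_mean) {
  if (length(y_test) != length(y_pred) || length(y_test) < 2)
    stop_data("y_test and y_pred must have equal length >= 2")
  sstot <- sum((y_test - y_train_mean)^2)
  if (sstot == 0) stop_numeric("denominator is zero")
  1 - sum((y_test - y_pred)^2) / sstot
}
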