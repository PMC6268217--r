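# Leverage-based applicability domain and Williams-plot outlier
# classification: hat values measure how far a compound sits from the
# training set in descriptor space, standardized residuals flag response
# outliers.

#' Leverage (hat) values of query compounds against a training design
#'
#' `h_i = x_i (X'X)^-1 x_i'` where `x_i` is the query row and `X` the
#' training design, both with an intercept column appended. Training rows
#' queried against themselves give the hat-matrix diagonal, which sums to
#' the number of model parameters.
#'
#' @param X_train Training descriptor matrix (model columns only).
#' @param X_query Query descriptor matrix with the same columns
#'   (default: the training matrix itself).
#' @return Numeric vector of leverages, one per query row.
#' @export
leverages <- function(X_train, X_query = X_train) {
  X_train <- as.matrix(X_train); X_query <- as.matrix(X_query)
  if (ncol(X_query) != ncol(X_train))
    stop_data("query and training matrices must share columns")
  Dt <- cbind(1, X_train)
  Dq <- cbind(1, X_query)
  XtX <- crossprod(Dt)
  inv <- tryCatch(solve(XtX), error = function(e)
    stop_numeric("singular X'X: ", conditionMessage(e)))
  rowSums((Dq %*% inv) * Dq)
}

#' Control leverage threshold h* = 3k/n
#'
#' @param k Number of model parameters, including the intercept.
#' @param n Number of training compounds.
#' @return `3 * k / n`.
#' @export
control_leverage <- function(k, n) {
  k <- check_count(k, "k"); n <- check_count(n, "n")
  3 * k / n
}

#' Standardized residuals
#'
#' Centered residuals divided by their standard deviation (internal
#' scaling, population form: `sqrt(mean((r - mean(r))^2))`, so a symmetric
#' `+c/-c` residual pattern maps exactly to +1/-1). OLS residuals have
#' mean zero, so centering changes nothing there. Compounds beyond 2.5 of
#' these "standard deviation units" are conventionally flagged as response
#' outliers. For external compounds pass the training residual `center`
#' and `scale` -- the training error scale is what the test compounds are
#' judged against.
#'
#' @param y Observed responses (length >= 3).
#' @param y_hat Fitted/predicted responses.
#' @param center,scale Optional reference location/scale; default the mean
#'   and population SD of `y - y_hat`.
#' @return Numeric vector of standardized residuals.
#' @export
standardized_residuals <- function(y, y_hat, center = NULL, scale = NULL) {
  if (length(y) != length(y_hat) || length(y) < 1)
    stop_data("y and y_hat must have equal length >= 1")
  if ((is.null(center) || is.null(scale)) && length(y) < 3)
    stop_data("need >= 3 residuals to estimate their own scale")
  r <- y - y_hat
  if (is.null(center)) center <- mean(r)
  if (is.null(scale)) scale <- sqrt(mean((r - center)^2))
  if (!is.finite(scale) || scale <= 0)
    stop_numeric("residual standard deviation is zero")
  (r - center) / scale
}

#' Williams-plot applicability-domain classification
#'
#' Labels every compound by leverage and standardized residual: a compound
#' with `h_i > h*` (default `h* = 3k/n`) is an X outlier -- its prediction
#' is a substantial extrapolation of the model; one with |standardized
#' residual| beyond `residual_cut` (default 2.5) is a Y outlier. Training
#' and external compounds are pooled under one `h*`, each labeled with its
#' set. External residuals are standardized by the *training* residual SD.
#'
#' @param model A fitted `mlr_model`.
#' @param train The training `qsar_dataset` the model was fitted on.
#' @param test Optional external `qsar_dataset` sharing the model's
#'   descriptor columns.
#' @param residual_cut SD-unit cutoff for Y outliers (default 2.5).
#' @param h_star Control leverage; default `3k/n` with k the number of
#'   model parameters including the intercept.
#' @return An object of class `ad_report`: a data frame with columns `id`,
#'   `set`, `leverage`, `std_residual`, `x_outlier`, `y_outlier`,
#'   `in_domain`, with `h_star` and `residual_cut` as attributes. The
#'   (leverage, standardized residual) pairs are the Williams-plot
#'   coordinates; [plot.ad_report()] renders them.
#' @export
williams_classify <- function(model, train, test = NULL, residual_cut = 2.5,
                              h_star = NULL) {
  stopifnot(inherits(model, "mlr_model"), inherits(train, "qsar_dataset"))
  missing <- setdiff(model$subset, colnames(train$X))
  if (length(missing))
    stop_data("training table lacks model descriptor(s): ",
              paste(missing, collapse = ", "))
  Xtr <- train$X[, model$subset, drop = FALSE]
  k <- model$p + 1L  # parameters including the constant term
  if (is.null(h_star)) h_star <- control_leverage(k, nrow(Xtr))
  h_tr <- leverages(Xtr)
  res_tr <- train$y - predict(model, train$X)
  ctr_tr <- mean(res_tr)
  sd_tr <- sqrt(mean((res_tr - ctr_tr)^2))
  sr_tr <- standardized_residuals(train$y, predict(model, train$X),
                                  center = ctr_tr, scale = sd_tr)
  rows <- data.frame(id = train$ids, set = "training", leverage = h_tr,
                     std_residual = sr_tr, stringsAsFactors = FALSE)
  if (!is.null(test)) {
    stopifnot(inherits(test, "qsar_dataset"))
    missing <- setdiff(model$subset, colnames(test$X))
    if (length(missing))
      stop_data("test table lacks model descriptor(s): ",
                paste(missing, collapse = ", "))
    Xte <- test$X[, model$subset, drop = FALSE]
    h_te <- leverages(Xtr, Xte)
    sr_te <- standardized_residuals(test$y, predict(model, test$X),
                                    center = ctr_tr, scale = sd_tr)
    rows <- rbind(rows, data.frame(id = test$ids, set = "test",
                                   leverage = h_te, std_residual = sr_te,
                                   stringsAsFactors = FALSE))
  }
  rows$x_outlier <- rows$leverage > h_star
  rows$y_outlier <- abs(rows$std_residual) > residual_cut
  rows$in_domain <- !rows$x_outlier & !rows$y_outlier
  structure(rows, h_star = h_star, residual_cut = residual_cut,
            class = c("ad_report", "data.frame"))
}

#' Williams plot
#'
#' Standardized residuals against leverages, with the control leverage
#' `h*` (vertical) and the residual cut (horizontal) thresholds drawn.
#'
#' @param x An `ad_report`.
#' @param ... Passed to [plot()].
#' @export
plot.ad_report <- function(x, ...) {
  h_star <- attr(x, "h_star"); cut <- attr(x, "residual_cut")
  pch <- ifelse(x$set == "training", 19, 1)
  ylim <- range(c(x$std_residual, -cut - 0.5, cut + 0.5))
  xlim <- range(c(x$leverage, h_star * 1.1, 0))
  plot(x$leverage, x$std_residual, pch = pch, xlab = "leverage (h)",
       ylab = "standardized residual", xlim = xlim, ylim = ylim, ...)
  graphics::abline(v = h_star, lty = 2)
  graphics::abline(h = c(-cut, cut), lty = 3)
  flag <- x$x_outlier | x$y_outlier
  if (any(flag))
    graphics::text(x$leverage[flag], x$std_residual[flag], x$id[flag],
                   pos = 2, cex = 0.7)
  invisible(x)
}
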