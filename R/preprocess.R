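# Descriptor preselection: near-constant, highly inter-correlated and
# zero-inflated columns are removed before the subset search. Removal is
# reversible by construction -- the original table is never modified, and
# the filter report records every removal with its reason.

#' Remove near-constant descriptors
#'
#' Drops every column whose sample standard deviation is strictly below
#' `threshold` (default 1e-5).
#'
#' @param table Descriptor matrix.
#' @param threshold Minimum sample SD a column must reach to survive.
#' @return A list with `table` (the filtered matrix, column order preserved)
#'   and `removed` (character vector of dropped descriptor names).
#' @export
filter_low_std <- function(table, threshold = 0.00001) {
  validate_descriptor_table(table)
  if (nrow(table) < 2) stop_data("need >= 2 compounds to compute a standard deviation")
  sds <- apply(table, 2, stats::sd)
  drop <- sds < threshold
  list(table = table[, !drop, drop = FALSE], removed = colnames(table)[drop])
}

#' Remove one of every highly inter-correlated descriptor pair
#'
#' Scans column pairs (j, k > j) in order; whenever `|Pearson R| >= cutoff`
#' the later column k is removed. The scan is greedy and deterministic, so
#' the surviving set is reproducible (and documented as order-dependent).
#'
#' @param table Descriptor matrix with no zero-variance columns (run
#'   [filter_low_std()] first).
#' @param cutoff Absolute-correlation threshold (default 0.95); pairs at or
#'   above it lose their later member.
#' @return A list with `table` and `removed`, a data frame with columns
#'   `kept`, `removed`, `abs_r` recording each deletion.
#' @export
filter_pairwise_correlation <- function(table, cutoff = 0.95) {
  validate_descriptor_table(table)
  if (nrow(table) < 3) stop_data("need >= 3 compounds for correlation filtering")
  sds <- apply(table, 2, stats::sd)
  if (any(sds == 0))
    stop_data("zero-variance column(s) present (",
              paste(colnames(table)[sds == 0], collapse = ", "),
              "); run filter_low_std() first")
  m <- ncol(table)
  kept <- removed <- character(0)
  absr <- numeric(0)
  keep <- rep(TRUE, m)
  if (m >= 2) {
    R <- abs(stats::cor(table))
    for (j in seq_len(m - 1)) {
      if (!keep[j]) next
      for (k in seq(j + 1, m)) {
        if (keep[k] && R[j, k] >= cutoff) {
          keep[k] <- FALSE
          kept <- c(kept, colnames(table)[j])
          removed <- c(removed, colnames(table)[k])
          absr <- c(absr, R[j, k])
        }
      }
    }
  }
  list(table = table[, keep, drop = FALSE],
       removed = data.frame(kept = kept, removed = removed, abs_r = absr,
                            stringsAsFactors = FALSE))
}

#' Remove zero-inflated descriptors
#'
#' Drops every column whose fraction of exact zeros is at least `fraction`
#' (default 0.90). Zeros are compared exactly (`== 0`), no epsilon.
#'
#' @param table Descriptor matrix.
#' @param fraction Zero-fraction at or above which a column is removed.
#' @return A list with `table` and `removed` (names).
#' @export
filter_zero_inflated <- function(table, fraction = 0.90) {
  validate_descriptor_table(table)
  zf <- colMeans(table == 0)
  drop <- zf >= fraction
  list(table = table[, !drop, drop = FALSE], removed = colnames(table)[drop])
}

#' Descriptor preselection pipeline
#'
#' Applies the three preselection filters in order: (1) near-constant
#' columns (SD below `std_threshold`), (2) pairwise correlation at or above
#' `correlation_cutoff`, (3) zero-inflated columns. Returns both the
#' filtered table and a complete, auditable filter report; the input table
#' is untouched so removed descriptors can be recovered at any time.
#'
#' @param table Descriptor matrix.
#' @param std_threshold,correlation_cutoff,zero_fraction Filter parameters;
#'   see the individual filters.
#' @return A list with `table` (filtered matrix) and `report` (class
#'   `filter_report`).
#' @export
preprocess_descriptors <- function(table, std_threshold = 0.00001,
                                   correlation_cutoff = 0.95,
                                   zero_fraction = 0.90) {
  validate_descriptor_table(table)
  original <- colnames(table)
  s1 <- filter_low_std(table, std_threshold)
  s2 <- filter_pairwise_correlation(s1$table, correlation_cutoff)
  s3 <- filter_zero_inflated(s2$table, zero_fraction)
  report <- structure(
    list(removed_by_std = s1$removed,
         removed_by_correlation = s2$removed,
         removed_by_zeros = s3$removed,
         surviving = colnames(s3$table),
         original = original,
         parameters = list(std_threshold = std_threshold,
                           correlation_cutoff = correlation_cutoff,
                           zero_fraction = zero_fraction)),
    class = "filter_report")
  stopifnot(length(report$surviving) + length(s1$removed) +
              nrow(s2$removed) + length(s3$removed) == length(original))
  list(table = s3$table, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  cat(sprintf("  original descriptors : %d\n", length(x$original)))
  cat(sprintf("  removed (SD < %g)    : %d\n",
              x$parameters$std_threshold, length(x$removed_by_std)))
  cat(sprintf("  removed (|R| >= %g)  : %d\n",
              x$parameters$correlation_cutoff, nrow(x$removed_by_correlation)))
  cat(sprintf("  removed (zeros >= %g): %d\n",
              x$parameters$zero_fraction, length(x$removed_by_zeros)))
  cat(sprintf("  surviving            : %d\n", length(x$surviving)))
  invisible(x)
}
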