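#' Read a descriptor table from delimited text
#'
#' Reads a comma-separated descriptor table (one row per compound, one named
#' numeric column per molecular descriptor, e.g. an E-Dragon export) into a
#' validated numeric matrix whose rownames are the compound identifiers.
#'
#' @param path Path to a CSV file with a header row.
#' @param id_column Name or position of the compound-identifier column
#'   (default: the first column).
#' @return A numeric matrix with compound ids as rownames and descriptor
#'   names as colnames. Row and column order of the file are preserved.
#' @details Duplicate compound ids, duplicate descriptor names, non-numeric
#'   or missing cells and empty tables are rejected with informative errors;
#'   missing values are never imputed.
#' @export
read_descriptor_table <- function(path, id_column = 1L) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) stop_data("empty descriptor table: ", path)
  if (is.character(id_column)) {
    if (!id_column %in% names(raw))
      stop_data("id column '", id_column, "' not present in ", path)
    idc <- match(id_column, names(raw))
  } else {
    idc <- as.integer(id_column)
  }
  ids <- as.character(raw[[idc]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_data("duplicate compound id(s): ", paste(unique(dup), collapse = ", "))
  vals <- raw[, -idc, drop = FALSE]
  X <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(ids, names(vals)))
  for (j in seq_len(ncol(vals))) {
    v <- vals[[j]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num))
    if (length(bad))
      stop_data("non-numeric or missing value in column '", names(vals)[j],
                "', row id '", ids[bad[1]], "'")
    X[, j] <- num
  }
  validate_descriptor_table(X)
  X
}

#' Validate a descriptor table
#'
#' Checks the descriptor-table contract: a numeric matrix with unique
#' compound ids (rownames), unique descriptor names (colnames), at least one
#' row and column, and all cells finite.
#'
#' @param X A numeric matrix.
#' @return `X`, invisibly, if valid; otherwise an error.
#' @export
validate_descriptor_table <- function(X) {
  if (!is.matrix(X) || !is.numeric(X)) stop_data("descriptor table must be a numeric matrix")
  if (nrow(X) < 1 || ncol(X) < 1) stop_data("descriptor table must have >= 1 row and column")
  if (is.null(rownames(X)) || anyDuplicated(rownames(X)))
    stop_data("descriptor table needs unique compound ids as rownames")
  if (is.null(colnames(X)) || anyDuplicated(colnames(X)))
    stop_data("descriptor table needs unique descriptor names as colnames")
  if (!all(is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1, ]
    stop_data("non-finite value at compound '", rownames(X)[bad[1]],
              "', descriptor '", colnames(X)[bad[2]], "'")
  }
  invisible(X)
}

#' Read an activity series (compound id, numeric response)
#'
#' @param path CSV file with a header row.
#' @param id_column Name/position of the id column (default first).
#' @param activity_column Name/position of the response column (default
#'   second), e.g. logRBA.
#' @return A named numeric vector (names = compound ids).
#' @export
read_activity <- function(path, id_column = 1L, activity_column = 2L) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop_data("empty activity table: ", path)
  grab <- function(col, what) {
    if (is.character(col)) {
      if (!col %in% names(raw)) stop_data(what, " column '", col, "' not in ", path)
      raw[[col]]
    } else raw[[as.integer(col)]]
  }
  ids <- as.character(grab(id_column, "id"))
  if (anyDuplicated(ids))
    stop_data("duplicate compound id(s) in activity file: ",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  y <- suppressWarnings(as.numeric(grab(activity_column, "activity")))
  if (any(!is.finite(y)))
    stop_data("non-finite activity for id '", ids[which(!is.finite(y))[1]], "'")
  names(y) <- ids
  y
}

#' Bundle a descriptor table and activity series into an aligned dataset
#'
#' Reorders the activity series into the row order of the descriptor table
#' so both components index compounds identically.
#'
#' @param table Descriptor table (numeric matrix, see
#'   [read_descriptor_table()]).
#' @param activity Named numeric response vector.
#' @return An object of class `qsar_dataset`: a list with elements `X`
#'   (descriptor matrix), `y` (aligned response) and `ids`.
#' @export
align_dataset <- function(table, activity) {
  validate_descriptor_table(table)
  if (is.null(names(activity))) stop_data("activity series must be named by compound id")
  missing <- setdiff(rownames(table), names(activity))
  if (length(missing))
    stop_data("compound id(s) missing from activity series: ",
              paste(missing, collapse = ", "))
  y <- activity[rownames(table)]
  if (any(!is.finite(y))) stop_data("non-finite activity after alignment")
  qsar_dataset(table, y)
}

#' Construct a qsar_dataset
#'
#' @param X Descriptor matrix (rownames = compound ids).
#' @param y Numeric response, same length and order as `nrow(X)`.
#' @return A `qsar_dataset` list with `X`, `y`, `ids`.
#' @export
qsar_dataset <- function(X, y) {
  validate_descriptor_table(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop_data("length(y) must equal nrow(X)")
  if (any(!is.finite(y))) stop_data("response must be finite")
  names(y) <- rownames(X)
  structure(list(X = X, y = y, ids = rownames(X)), class = "qsar_dataset")
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat(sprintf("<qsar_dataset> %d compounds x %d descriptors\n",
              nrow(x$X), ncol(x$X)))
  cat("  response range:", paste(signif(range(x$y), 4), collapse = " .. "), "\n")
  invisible(x)
}

#' Write a dataset to a CSV pair
#'
#' Writes the descriptor table and the activity series of a `qsar_dataset`
#' as two CSV files whose first column is the compound id. Numbers are
#' written at full precision so a write/read round trip is exact.
#'
#' @param data A `qsar_dataset`.
#' @param descriptor_path,activity_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(data, descriptor_path, activity_path) {
  stopifnot(inherits(data, "qsar_dataset"))
  dtab <- data.frame(compound_id = data$ids, data$X,
                     check.names = FALSE, stringsAsFactors = FALSE)
  write_full_precision(dtab, descriptor_path)
  atab <- data.frame(compound_id = data$ids, activity = unname(data$y),
                     stringsAsFactors = FALSE)
  write_full_precision(atab, activity_path)
  invisible(c(descriptor_path, activity_path))
}

# CSV writer preserving >= 17 significant digits for numeric columns.
write_full_precision <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  ok <- tryCatch(suppressWarnings({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }), error = function(e) FALSE)
  if (!ok) stop_data("cannot write file: ", path)
  invisible(path)
}
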