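# Structured run reports: one canonical JSON document, versioned, written
# and read with jsonlite so a write/read cycle is the identity (numbers are
# serialized at full precision).

REPORT_SCHEMA_VERSION <- "1.0"

#' Write a structured run report
#'
#' Serializes a run summary (selected subsets, model statistics, CV
#' summaries, applicability-domain classifications, ...) to a single JSON
#' document that [read_report()] loads back.
#'
#' @param results A named list; typically the value of [run_pipeline()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(results, path) {
  if (!is.list(results) || is.null(names(results)) || length(results) == 0)
    stop_data("report must be a non-empty named list")
  doc <- c(list(schema_version = REPORT_SCHEMA_VERSION), results)
  ok <- tryCatch(suppressWarnings({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
    TRUE
  }), error = function(e) FALSE)
  if (!ok) stop_data("cannot write report to: ", path)
  invisible(path)
}

#' Read a structured run report
#'
#' @param path Path to a JSON report written by [write_report()].
#' @return The report as a named list (without the schema marker).
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_data("report not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version))
    stop_data("not a vsmvi report (missing schema_version): ", path)
  doc$schema_version <- NULL
  doc
}
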