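# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-stage seed derivation from one global seed, kept inside
# the 32-bit integer range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  stages <- c(simulate = 1L, preprocess = 2L, search = 3L, cv_final = 4L,
              randomization = 5L, domain = 6L)
  k <- stages[[stage]]
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("vsmvi_data_error", "error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("vsmvi_numeric_error", "error")))
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != floor(x) || x < min)
    stop(sprintf("`%s` must be a single integer >= %s", name, min))
  as.integer(x)
}
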