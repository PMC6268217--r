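# The VSMVI search: exhaustive scans of low-order subsets (sizes up to Na),
# then interaction-driven extension of the retained pool of optimal
# (vn-1)-subsets by one variable at a time. Candidate subsets are gated by
# the pairwise-correlation threshold r_int and a size-dependent minimum
# training r2 (r_cri) before the expensive cross-validation score (SC) is
# computed; the fixed-capacity pool keeps the Ns best subsets by SC,
# displacing the current minimum (SC_min). The inner loop is compiled; the
# search is deterministic given the shared split plan.

#' Search configuration for [run_vsmvi()]
#'
#' @param vm Maximum subset size to consider (default 15). The effective
#'   cap is `min(vm, floor(n/5))`, so model size never exceeds one fifth of
#'   the number of compounds.
#' @param r_int Maximum allowed pairwise descriptor |correlation| inside a
#'   subset (default 0.9; stricter practice uses 0.75). A subset containing
#'   a pair at or above `r_int` is skipped before any model is fitted.
#' @param r_cri_initial Minimum training r2 gate for single-descriptor
#'   subsets (default 0.1); the gate grows with subset size.
#' @param r_cri Optional explicit gate schedule: a numeric vector indexed
#'   by subset size, or a function of the size. Default:
#'   `min(0.8, r_cri_initial * vn)` -- increasing with the number of
#'   variables, capped so candidates are never all gated out.
#' @param Ns Pool capacity: number of optimal subsets retained per size
#'   (default 1000).
#' @param Na Largest size handled by the exhaustive stage (default 3);
#'   larger sizes use pool extension.
#' @param sc_kind Stop-criterion flavor: `"q2"` (mean LMOCV q2, maximized;
#'   default) or `"rmsev"` (mean LMOCV RMSEV, minimized).
#' @param cv_fraction,cv_N Parameters of the shared MCCV split plan
#'   (default two-fold, 100 splits).
#' @param seed Integer seed; governs only the split plan -- given the plan,
#'   the search is deterministic.
#' @return An object of class `vsmvi_config`.
#' @export
vsmvi_config <- function(vm = 15, r_int = 0.9, r_cri_initial = 0.1,
                         r_cri = NULL, Ns = 1000, Na = 3,
                         sc_kind = c("q2", "rmsev"),
                         cv_fraction = 0.5, cv_N = 100, seed = NULL) {
  sc_kind <- match.arg(sc_kind)
  vm <- check_count(vm, "vm"); Ns <- check_count(Ns, "Ns")
  Na <- check_count(Na, "Na")
  if (!is.numeric(r_int) || r_int <= 0 || r_int > 1)
    stop_data("r_int must be in (0, 1]")
  schedule <- if (is.null(r_cri)) {
    function(vn) pmin(0.8, r_cri_initial * vn)
  } else if (is.function(r_cri)) {
    r_cri
  } else {
    sched <- as.numeric(r_cri)
    function(vn) sched[pmin(vn, length(sched))]
  }
  structure(list(vm = vm, r_int = r_int, r_cri_initial = r_cri_initial,
                 r_cri = schedule, Ns = Ns, Na = Na, sc_kind = sc_kind,
                 cv_fraction = cv_fraction, cv_N = cv_N, seed = seed),
            class = "vsmvi_config")
}

as_pool <- function(raw, vn, names, r_cri) {
  idx <- raw$indices
  structure(list(size = vn,
                 indices = idx,
                 names = if (nrow(idx)) apply(idx, 1, function(i) names[i],
                                              simplify = FALSE) else list(),
                 sc = raw$sc, r2 = raw$r2, r_cri = r_cri,
                 counts = raw$counts),
            class = "subset_pool")
}

#' @export
print.subset_pool <- function(x, ...) {
  cat(sprintf("<subset_pool> size %d, %d record(s)\n", x$size, length(x$sc)))
  if (length(x$sc)) {
    cat(sprintf("  best SC = %.4f (r2 = %.4f): %s\n", x$sc[1], x$r2[1],
                paste(x$names[[1]], collapse = ", ")))
  }
  invisible(x)
}

check_search_inputs <- function(data, config) {
  stopifnot(inherits(data, "qsar_dataset"), inherits(config, "vsmvi_config"))
  invisible(NULL)
}

#' Exhaustive screening of all size-vn subsets
#'
#' Visits every size-`vn` descriptor combination in lexicographic order; a
#' combination is scored only when (a) all pairwise |r| are strictly below
#' `r_int` and (b) its training r2 clears the size-`vn` gate. The pool
#' retains the `Ns` best scored subsets.
#'
#' @param data A `qsar_dataset`.
#' @param vn Subset size (must not exceed `config$Na`).
#' @param config A `vsmvi_config`.
#' @param plan Shared `split_plan` for the stop-criterion CV.
#' @return A `subset_pool` (records ordered best-first) with a `counts`
#'   vector tracing generated/gated/scored candidates.
#' @export
exhaustive_stage <- function(data, vn, config = vsmvi_config(), plan) {
  check_search_inputs(data, config)
  vn <- check_count(vn, "vn")
  if (vn > config$Na)
    stop_data("vn = ", vn, " exceeds Na = ", config$Na, "; use extension_stage()")
  r_cri <- config$r_cri(vn)
  raw <- cpp_exhaustive_stage(data$X, data$y, vn, plan$validation,
                              config$r_int, r_cri, config$Ns,
                              config$sc_kind == "q2")
  pool <- as_pool(raw, vn, colnames(data$X), r_cri)
  if (length(pool$sc) == 0)
    warning("no size-", vn, " subset passed the gates; pool is empty")
  pool
}

#' Extend a pool of (vn-1)-subsets by one variable (interaction stage)
#'
#' Every subset in the parent pool is combined with each descriptor absent
#' from it; children are deduplicated by sorted index set, gated by `r_int`
#' and the size-vn r2 gate, scored by the shared-plan stop criterion, and
#' pool-inserted under the SC_min replacement rule.
#'
#' @param data A `qsar_dataset`.
#' @param parent_pool A non-empty `subset_pool` of size vn - 1.
#' @param config A `vsmvi_config`.
#' @param plan Shared `split_plan`.
#' @return A `subset_pool` of size vn.
#' @export
extension_stage <- function(data, parent_pool, config = vsmvi_config(), plan) {
  check_search_inputs(data, config)
  stopifnot(inherits(parent_pool, "subset_pool"))
  if (length(parent_pool$sc) == 0) stop_data("parent pool is empty")
  vn <- parent_pool$size + 1L
  r_cri <- config$r_cri(vn)
  raw <- cpp_extension_stage(data$X, data$y, parent_pool$indices,
                             plan$validation, config$r_int, r_cri,
                             config$Ns, config$sc_kind == "q2")
  pool <- as_pool(raw, vn, colnames(data$X), r_cri)
  if (length(pool$sc) == 0)
    warning("all size-", vn, " children were gated out; pool is empty")
  pool
}

#' Run the full VSMVI search
#'
#' Processes subset sizes `1 .. min(vm, floor(n/5))`: exhaustively for
#' sizes up to `Na`, by pool extension beyond. All sizes share one MCCV
#' split plan so candidate subsets are compared on identical splits.
#'
#' @param data A preprocessed `qsar_dataset` with `n >= 10` compounds.
#' @param config A `vsmvi_config`.
#' @return An object of class `vsmvi_result`: `pools` (one `subset_pool`
#'   per size), `trace` (a data frame of candidate counts per size), the
#'   shared `plan`, the `config` and the descriptor names.
#' @export
run_vsmvi <- function(data, config = vsmvi_config()) {
  check_search_inputs(data, config)
  n <- nrow(data$X); m <- ncol(data$X)
  if (n < 10) stop_data("need at least 10 compounds for a search (n = ", n, ")")
  kmax <- min(config$vm, floor(n / 5))
  plan <- make_mccv_splits(n, config$cv_fraction, config$cv_N,
                           seed = config$seed)
  pools <- vector("list", kmax)
  trace <- vector("list", kmax)
  for (vn in seq_len(kmax)) {
    pool <- if (vn <= config$Na) {
      exhaustive_stage(data, vn, config, plan)
    } else {
      parent <- pools[[vn - 1]]
      if (is.null(parent) || length(parent$sc) == 0) {
        warning("size-", vn - 1, " pool is empty; stopping search at size ", vn - 1)
        break
      }
      extension_stage(data, parent, config, plan)
    }
    pools[[vn]] <- pool
    trace[[vn]] <- data.frame(size = vn, stage = if (vn <= config$Na)
      "exhaustive" else "extension", t(pool$counts),
      pool_size = length(pool$sc),
      best_sc = if (length(pool$sc)) pool$sc[1] else NA_real_)
  }
  done <- !vapply(pools, is.null, logical(1))
  structure(list(pools = pools[done], trace = do.call(rbind, trace),
                 plan = plan, config = config,
                 descriptor_names = colnames(data$X)),
            class = "vsmvi_result")
}

#' @export
print.vsmvi_result <- function(x, ...) {
  cat(sprintf("<vsmvi_result> sizes 1..%d over %d descriptors\n",
              length(x$pools), length(x$descriptor_names)))
  print(x$trace[, c("size", "stage", "generated", "scored", "pool_size", "best_sc")],
        row.names = FALSE)
  invisible(x)
}

#' Best subset at a given size
#'
#' @param result A `vsmvi_result`.
#' @param size Subset size; default the largest searched size.
#' @return List with `indices`, `names`, `sc`, `r2` of the top pool record.
#' @export
best_subset <- function(result, size = NULL) {
  stopifnot(inherits(result, "vsmvi_result"))
  if (is.null(size)) size <- length(result$pools)
  pool <- result$pools[[size]]
  if (is.null(pool) || length(pool$sc) == 0)
    stop_data("no records at size ", size)
  list(indices = pool$indices[1, ], names = pool$names[[1]],
       sc = pool$sc[1], r2 = pool$r2[1])
}

#' Stop-criterion curve across subset sizes
#'
#' @param result A `vsmvi_result`.
#' @return Named numeric vector: best SC (mean LMOCV q2 by default) per
#'   size, suitable for [select_model_size()].
#' @export
cv_curve <- function(result) {
  stopifnot(inherits(result, "vsmvi_result"))
  vapply(result$pools, function(p)
    if (length(p$sc)) p$sc[1] else NA_real_, numeric(1)) |>
    stats::setNames(seq_along(result$pools))
}

#' Pick the model size from a cross-validation curve
#'
#' Returns the smallest size k whose relative stop-criterion gain going to
#' k + 1 falls below `threshold` (default 5%): once enlarging the model
#' buys less than that, the smaller model is preferred. A non-positive gain
#' also stops. If every gain stays above the threshold the largest size
#' available is returned.
#'
#' @param q2_by_size Numeric vector of mean CV q2 for consecutive sizes
#'   starting at 1 (at least 2 entries).
#' @param threshold Relative-gain cutoff (default 0.05).
#' @return The selected size (integer).
#' @export
select_model_size <- function(q2_by_size, threshold = 0.05) {
  q2 <- as.numeric(q2_by_size)
  if (length(q2) < 2) stop_data("need q2 values for at least 2 sizes")
  for (k in seq_len(length(q2) - 1)) {
    gain <- q2[k + 1] - q2[k]
    if (gain <= 0) return(k)
    if (gain / abs(q2[k]) < threshold) return(k)
  }
  length(q2)
}

#' Number of combinations an all-subsets scan must evaluate
#'
#' The binomial coefficient `C(m, k)`, computed by the exact multiplicative
#' scheme (each intermediate product is an integer).
#'
#' @param m Pool size; @param k Subset size (`0 <= k <= m`).
#' @return The exact count as a numeric.
#' @export
count_asr_combinations <- function(m, k) {
  m <- check_count(m, "m", min = 0); k <- check_count(k, "k", min = 0)
  if (k > m) stop_data("k must not exceed m")
  res <- 1
  for (i in seq_len(min(k, m - k))) res <- res * (m - min(k, m - k) + i) / i
  round(res)
}

#' Candidate evaluations in one VSMVI extension step
#'
#' The pool-extension accounting: `Ns * m` candidate evaluations, an upper
#' bound (deduplication and gating reduce the actual work, which the search
#' trace records).
#'
#' @param m Number of descriptors; @param Ns Pool capacity.
#' @return `m * Ns` as a numeric.
#' @export
count_vsmvi_combinations <- function(m, Ns) {
  m <- check_count(m, "m"); Ns <- check_count(Ns, "Ns")
  as.numeric(m) * as.numeric(Ns)
}
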