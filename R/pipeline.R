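# End-to-end pipeline: (simulate |) load -> preprocess -> search -> final
# model -> y-randomization -> applicability domain -> report. All numbers
# in the report come from the module functions; the pipeline only wires
# them together.

#' Assemble and validate a pipeline configuration
#'
#' @param descriptors,activity Paths to the training descriptor/activity
#'   CSV files (ignored when `simulate` is given).
#' @param test_descriptors,test_activity Optional external-test paths.
#' @param simulate Optional list of arguments for
#'   [generate_qsar_dataset()]; when present the pipeline runs on a
#'   simulated dataset instead of files.
#' @param output Path of the JSON run report (`NULL` = don't write).
#' @param preprocess,search,cv,validation,domain Named lists of module
#'   parameters: `preprocess` feeds [preprocess_descriptors()]; `search`
#'   feeds [vsmvi_config()]; `cv$N_final` sets the split count for final
#'   reporting (default 1000); `validation$runs` the y-randomization count
#'   (default 1000); `domain$residual_cut` the Y-outlier cutoff.
#' @param size_threshold Relative-gain cutoff for [select_model_size()].
#' @param seed Global integer seed, fanned out deterministically to the
#'   simulate/search/final-CV/randomization stages so each stage is
#'   independently reproducible.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(descriptors = NULL, activity = NULL,
                       test_descriptors = NULL, test_activity = NULL,
                       simulate = NULL, output = NULL,
                       preprocess = list(), search = list(), cv = list(),
                       validation = list(), domain = list(),
                       size_threshold = 0.05, seed = 1L) {
  cfg <- list(descriptors = descriptors, activity = activity,
              test_descriptors = test_descriptors,
              test_activity = test_activity, simulate = simulate,
              output = output, preprocess = preprocess, search = search,
              cv = cv, validation = validation, domain = domain,
              size_threshold = size_threshold, seed = seed)
  problems <- character(0)
  if (is.null(simulate)) {
    for (f in c("descriptors", "activity")) {
      if (is.null(cfg[[f]]))
        problems <- c(problems, sprintf("`%s` is required without `simulate`", f))
      else if (!file.exists(cfg[[f]]))
        problems <- c(problems, sprintf("`%s` file not found: %s", f, cfg[[f]]))
    }
    for (f in c("test_descriptors", "test_activity"))
      if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
        problems <- c(problems, sprintf("`%s` file not found: %s", f, cfg[[f]]))
  }
  for (f in c("preprocess", "search", "cv", "validation", "domain"))
    if (!is.list(cfg[[f]]))
      problems <- c(problems, sprintf("`%s` must be a named list", f))
  if (!is.numeric(size_threshold) || size_threshold <= 0)
    problems <- c(problems, "`size_threshold` must be positive")
  if (length(problems))
    stop_data("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_data("config file not found: ", path)
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full VSMVI pipeline
#'
#' Executes: data loading (or simulation), descriptor preselection, the
#' VSMVI search, model-size selection by the <5%-gain rule, the final MLR
#' model with LOOCV / final LMOCV / external-test statistics,
#' y-randomization with the c r2p statistic, and Williams-plot
#' applicability-domain classification. Per-stage progress goes to
#' standard error; the only file output is the report.
#'
#' @param config A `run_config` (or a YAML path understood by
#'   [read_run_config()]).
#' @param quiet Suppress progress messages.
#' @return The run report (a named list), invisibly written to
#'   `config$output` when set.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[vsmvi] ", ...)

  if (!is.null(config$simulate)) {
    args <- config$simulate
    if (is.null(args$seed)) args$seed <- derive_seed(config$seed, "simulate")
    say("simulating dataset (seed ", args$seed, ")")
    sim <- do.call(generate_qsar_dataset, args)
    train_raw <- sim$train; test <- sim$test
    truth <- sim$truth
  } else {
    say("loading ", config$descriptors)
    table <- read_descriptor_table(config$descriptors)
    activity <- read_activity(config$activity)
    train_raw <- align_dataset(table, activity)
    test <- NULL
    if (!is.null(config$test_descriptors)) {
      ttab <- read_descriptor_table(config$test_descriptors)
      tact <- read_activity(config$test_activity)
      test <- align_dataset(ttab, tact)
    }
    truth <- NULL
  }

  say("preprocessing ", ncol(train_raw$X), " descriptors")
  pre <- do.call(preprocess_descriptors,
                 c(list(table = train_raw$X), config$preprocess))
  train <- qsar_dataset(pre$table, train_raw$y)
  say("  ", length(pre$report$surviving), " survive preselection")

  search_args <- config$search
  if (is.null(search_args$seed))
    search_args$seed <- derive_seed(config$seed, "search")
  scfg <- do.call(vsmvi_config, search_args)
  say("searching subsets (sizes 1..", min(scfg$vm, floor(nrow(train$X) / 5)),
      ", Ns = ", scfg$Ns, ")")
  t0 <- proc.time()[["elapsed"]]
  search <- run_vsmvi(train, scfg)
  say(sprintf("  search done in %.1f s", proc.time()[["elapsed"]] - t0))

  curve <- cv_curve(search)
  size <- if (length(curve) >= 2) select_model_size(curve, config$size_threshold)
          else length(curve)
  top <- best_subset(search, size)
  say("selected model size ", size, ": ", paste(top$names, collapse = ", "))

  Xsub <- train$X[, top$names, drop = FALSE]
  model <- fit_mlr(Xsub, train$y)
  loo <- loocv(Xsub, train$y)
  N_final <- config$cv$N_final %||% 1000
  plan_final <- make_mccv_splits(nrow(Xsub), scfg$cv_fraction, N_final,
                                 seed = derive_seed(config$seed, "cv_final"))
  say("final LMOCV (", N_final, " splits) and y-randomization")
  mccv <- lmocv(Xsub, train$y, plan_final)

  runs <- config$validation$runs %||% 1000
  yr <- y_randomization(Xsub, train$y, runs = runs, plan = plan_final,
                        seed = derive_seed(config$seed, "randomization"))
  crp <- tryCatch(crp_statistic(model$r2, yr$r2_mean),
                  error = function(e) NA_real_)

  external <- NULL
  if (!is.null(test)) {
    pred <- predict(model, test$X)
    external <- list(q2 = external_q2(test$y, pred),
                     rmsep = rmse(test$y, pred))
  }

  cut <- config$domain$residual_cut %||% 2.5
  ad <- williams_classify(model, train, test, residual_cut = cut)

  report <- list(
    seed = config$seed,
    preprocess = list(
      original = length(pre$report$original),
      surviving = length(pre$report$surviving),
      removed_by_std = pre$report$removed_by_std,
      removed_by_correlation = pre$report$removed_by_correlation,
      removed_by_zeros = pre$report$removed_by_zeros),
    search = list(trace = search$trace, cv_curve = unname(curve),
                  pools = lapply(search$pools, function(p)
                    list(size = p$size,
                         records = head(data.frame(
                           subset = vapply(p$names, paste, "", collapse = "+"),
                           sc = p$sc, r2 = p$r2), 25)))),
    model = list(size = size, subset = top$names,
                 coefficients = as.list(model$coefficients),
                 standardized_coefficients =
                   as.list(standardized_coefficients(model, Xsub, train$y)),
                 r2 = model$r2, rmse = model$rmse, f_stat = model$f_stat),
    cross_validation = list(
      loocv = list(q2 = loo$q2_mean, rmsev = loo$rmsev_mean),
      lmocv = list(q2_mean = mccv$q2_mean, q2_std = mccv$q2_std,
                   rmsev_mean = mccv$rmsev_mean, rmsev_std = mccv$rmsev_std,
                   N = N_final)),
    external = external,
    y_randomization = list(runs = yr$runs, r2_mean = yr$r2_mean,
                           q2_mean = yr$q2_mean,
                           q2_below_zero = mean(yr$q2_values < 0),
                           crp = crp),
    applicability_domain = list(
      h_star = attr(ad, "h_star"), residual_cut = attr(ad, "residual_cut"),
      compounds = as.data.frame(ad)),
    truth = truth)
  report <- report[!vapply(report, is.null, logical(1))]

  if (!is.null(config$output)) {
    write_report(report, config$output)
    say("report written to ", config$output)
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
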