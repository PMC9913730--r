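#' Configuration for the end-to-end fever-detection pipeline
#'
#' Bundles the per-stage settings. Every default matches the analysis
#' constants: 30/45 degC extreme bounds, 1.0 degC jump threshold, the
#' 1.0 degC / 4 h fever rule, windows of 3, 6, 12, 24 and 48 h, 100 trees,
#' an 80/20 split with repeated 10-fold cross-validation and a 0.5
#' probability threshold.
#'
#' @param sim a [sim_config()] for the synthetic dataset.
#' @param low,high,max_step preprocessing thresholds, degC.
#' @param min_coverage,lookback_days,min_baseline_days transform settings.
#' @param threshold,run_length,confirmed_only fever-rule settings.
#' @param windows,min_window_coverage feature-extraction settings.
#' @param feature_input series the features are computed on:
#'   `"estimated_rst"` (default) or `"raw"`.
#' @param use_metadata include arrival metadata features.
#' @param n_trees,test_fraction,cv_folds,cv_repeats,prob_threshold,split_unit,cross_validate
#'   classifier protocol; see [fever_rf()].
#' @param seed global seed; per-stage seeds are derived from it.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            low = 30, high = 45, max_step = 1.0,
                            min_coverage = 0.5, lookback_days = 3,
                            min_baseline_days = 2,
                            threshold = 1.0, run_length = 4,
                            confirmed_only = FALSE,
                            windows = c(3, 6, 12, 24, 48),
                            min_window_coverage = 0.5,
                            feature_input = c("estimated_rst", "raw"),
                            use_metadata = FALSE,
                            n_trees = 100, test_fraction = 0.2,
                            cv_folds = 10, cv_repeats = 3,
                            prob_threshold = 0.5,
                            split_unit = c("record", "calf"),
                            cross_validate = TRUE,
                            seed = 1L) {
  stopifnot(inherits(sim, "sim_config"))
  cfg <- list(sim = sim, low = low, high = high, max_step = max_step,
              min_coverage = min_coverage, lookback_days = lookback_days,
              min_baseline_days = min_baseline_days, threshold = threshold,
              run_length = run_length, confirmed_only = confirmed_only,
              windows = windows, min_window_coverage = min_window_coverage,
              feature_input = match.arg(feature_input),
              use_metadata = isTRUE(use_metadata),
              n_trees = n_trees, test_fraction = test_fraction,
              cv_folds = cv_folds, cv_repeats = cv_repeats,
              prob_threshold = prob_threshold,
              split_unit = match.arg(split_unit),
              cross_validate = isTRUE(cross_validate),
              seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' Read or write a pipeline configuration as a single YAML file
#'
#' @param path file path.
#' @return `read_pipeline_config()` returns a validated [pipeline_config()];
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  sim <- if (is.null(vals$sim)) sim_config() else do.call(sim_config, vals$sim)
  vals$sim <- NULL
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown pipeline configuration field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, c(list(sim = sim), vals))
}

#' @param config a `pipeline_config`.
#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  vals <- unclass(config)
  vals$sim <- unclass(vals$sim)
  yaml::write_yaml(vals, path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full fever-detection pipeline
#'
#' Composes every stage in its fixed order: simulate, preprocess (extreme and
#' jump filters, hourly maxima), transform (estimated ST, residuals), label
#' (sustained-elevation rule), featurize (rolling windows, optional
#' metadata), then split/cross-validate/train/evaluate the random forest.
#' With an `output_dir`, all intermediates are written as CSV, the evaluation
#' report as JSON, and a run manifest (config echo, seed, package version)
#' alongside; partial outputs are retained if a later stage fails.
#'
#' @param config a [pipeline_config()].
#' @param output_dir optional directory for artifacts (created if missing).
#' @param quiet suppress progress messages.
#' @return the fitted [fever_rf()] model, with the simulation attached as
#'   attribute `"sim"` and the labels as `"labels"`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  emit <- function(fun, obj, file, ...) {
    if (!is.null(output_dir)) fun(obj, file.path(output_dir, file), ...)
  }
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }

  sim_cfg <- config$sim
  sim_cfg$seed <- derive_seed(config$seed, 0)
  sim_cfg <- do.call(sim_config, unclass(sim_cfg))

  say("simulate: ", sim_cfg$n_calves, " calves x ", sim_cfg$duration_days,
      " days")
  sim <- stage("simulate", simulate_calves(sim_cfg))
  emit(write_sensor_csv, sim$traces, "traces.csv")
  emit(write_episodes_csv, sim$episodes, "episodes.csv")
  emit(write_metadata_csv, sim$metadata, "metadata.csv")

  say("preprocess: ", nrow(sim$traces), " records")
  hourly <- stage("preprocess",
                  preprocess_st(sim$traces, config$low, config$high,
                                config$max_step))

  say("transform: ", nrow(hourly), " calf-hours")
  tf <- stage("transform",
              st_transforms(hourly, config$min_coverage, config$lookback_days,
                            config$min_baseline_days))
  erst <- measurement_series(tf, "estimated_rst")
  if (nrow(erst) == 0L) {
    stop("pipeline stage 'transform': no defined estimated rST values ",
         "(trace shorter than the residual lookback?)", call. = FALSE)
  }

  labels <- stage("label",
                  label_fever(erst, config$threshold, config$run_length,
                              config$confirmed_only))
  emit(write_labels_csv, labels, "labels.csv")
  say("label: ", sum(labels$label == 1L), " fever hours of ", nrow(labels))

  feat_in <- if (config$feature_input == "raw") {
    measurement_series(tf, "raw")
  } else {
    erst
  }
  features <- stage("featurize", {
    ft <- extract_features(feat_in, config$windows,
                           config$min_window_coverage)
    attach_labels_and_metadata(ft, labels, sim$metadata,
                               config$use_metadata)
  })
  emit(write_features_csv, features, "features.csv", seed = config$seed,
       config = config)
  say("featurize: ", nrow(features), " rows x ",
      length(feature_names(features)), " features")

  model <- stage("model",
                 fever_rf(features, n_trees = config$n_trees,
                          test_fraction = config$test_fraction,
                          cv_folds = config$cv_folds,
                          cv_repeats = config$cv_repeats,
                          prob_threshold = config$prob_threshold,
                          split_unit = config$split_unit,
                          cross_validate = config$cross_validate,
                          seed = derive_seed(config$seed, 101)))
  emit(write_report, model, "report.json")
  if (!is.null(output_dir)) {
    manifest <- list(
      package = "calffever",
      version = as.character(utils::packageVersion("calffever")),
      seed = config$seed,
      config = local({
        v <- unclass(config); v$sim <- unclass(v$sim); v
      }))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  attr(model, "sim") <- sim
  attr(model, "labels") <- labels
  model
}
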