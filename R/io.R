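ts_format <- "%Y-%m-%dT%H:%M:%S"

format_ts <- function(ts) format(ts, ts_format, tz = "UTC")

parse_ts <- function(x) {
  out <- as.POSIXct(x, format = ts_format, tz = "UTC")
  alt <- is.na(out) & !is.na(x)
  if (any(alt)) {  # accept a space separator as well
    out[alt] <- as.POSIXct(x[alt], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  }
  out
}

#' Read and write sensor surface-temperature records as CSV
#'
#' The sensor CSV dialect has the header `calf_id,timestamp,temp_c` with
#' ISO-8601 timestamps (timezone-naive farm-local clock time). Reading
#' validates every row and names the offending line (header = line 1) on
#' failure; writing then reading a valid data.frame is the identity.
#'
#' @param path file path.
#' @return `read_sensor_csv()`: data.frame `calf_id`, `timestamp` (POSIXct),
#'   `temp_c`; `write_sensor_csv()`: `path`, invisibly.
#' @export
read_sensor_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("calf_id", "timestamp", "temp_c")
  if (!identical(names(df), need)) {
    stop("sensor CSV must have header ", paste(need, collapse = ","),
         call. = FALSE)
  }
  ts <- parse_ts(df$timestamp)
  bad <- which(is.na(ts))
  if (length(bad)) {
    stop("unparseable timestamp at line ", bad[1L] + 1L, ": '",
         df$timestamp[bad[1L]], "'", call. = FALSE)
  }
  temp <- suppressWarnings(as.numeric(df$temp_c))
  bad <- which(is.na(temp))
  if (length(bad)) {
    stop("unparseable temperature at line ", bad[1L] + 1L, ": '",
         df$temp_c[bad[1L]], "'", call. = FALSE)
  }
  data.frame(calf_id = df$calf_id, timestamp = ts, temp_c = temp,
             stringsAsFactors = FALSE)
}

#' @param traces data.frame `calf_id`, `timestamp`, `temp_c`.
#' @rdname read_sensor_csv
#' @export
write_sensor_csv <- function(traces, path) {
  out <- data.frame(calf_id = traces$calf_id,
                    timestamp = format_ts(traces$timestamp),
                    temp_c = traces$temp_c)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write fever-episode tables as CSV
#'
#' Dialect: `calf_id,start_time,end_time,magnitude_c`, ISO-8601 timestamps.
#'
#' @param path file path.
#' @param episodes data.frame `calf_id`, `start_time`, `end_time`,
#'   `magnitude_c`.
#' @return the episodes data.frame, or `path` invisibly.
#' @export
read_episodes_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  data.frame(calf_id = df$calf_id, start_time = parse_ts(df$start_time),
             end_time = parse_ts(df$end_time),
             magnitude_c = as.numeric(df$magnitude_c),
             stringsAsFactors = FALSE)
}

#' @rdname read_episodes_csv
#' @export
write_episodes_csv <- function(episodes, path) {
  out <- data.frame(calf_id = episodes$calf_id,
                    start_time = format_ts(episodes$start_time),
                    end_time = format_ts(episodes$end_time),
                    magnitude_c = episodes$magnitude_c)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write per-calf metadata as CSV
#'
#' Columns: `calf_id`, `sex`, `season_at_introduction`, `arrival_age_days`,
#' `arrival_weight_kg`, `chest_circumference_cm`, `blood_line`.
#'
#' @param path file path.
#' @param metadata per-calf metadata data.frame.
#' @return the metadata data.frame, or `path` invisibly.
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- c("arrival_age_days", "arrival_weight_kg", "chest_circumference_cm")
  for (nm in num) df[[nm]] <- as.numeric(df[[nm]])
  df
}

#' @rdname read_metadata_csv
#' @export
write_metadata_csv <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write hourly fever labels as CSV
#'
#' Dialect: `calf_id,timestamp,label`.
#'
#' @param labels data.frame from [label_fever()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(labels, path) {
  out <- data.frame(calf_id = labels$calf_id,
                    timestamp = format_ts(labels$hour), label = labels$label)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a feature table as CSV with a JSON manifest
#'
#' The sidecar manifest (`<path>.manifest.json`) records the feature-name
#' vector, window lengths and, when given, the generating seed and a config
#' echo, so a feature file is self-describing.
#'
#' @param table a `feature_table`.
#' @param path file path for the CSV.
#' @param seed,config optional provenance to embed in the manifest.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(table, path, seed = NULL, config = NULL) {
  out <- as.data.frame(table)
  out$hour <- format_ts(out$hour)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  plain <- NULL
  if (!is.null(config)) {
    plain <- unclass(config)
    plain <- lapply(plain, function(v) if (is.object(v)) unclass(v) else v)
  }
  manifest <- list(feature_names = feature_names(table),
                   windows = attr(table, "windows"),
                   n_rows = nrow(table), seed = seed,
                   config = plain)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' Serialize an evaluation report (plus context) as JSON
#'
#' @param report an `eval_report` or a fitted `fever_rf` (whose held-out
#'   report, CV summary and importances are all written).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "fever_rf")) {
    rep <- unclass(report$report)
    x <- list(
      counts = rep[c("tp", "tn", "fp", "fn")],
      metrics = rep[c("accuracy", "precision", "sensitivity")],
      n_test = rep$n,
      cv_means = if (!is.null(report$cv)) as.list(report$cv$means),
      importances = as.list(report$importance),
      protocol = list(n_trees = report$n_trees,
                      test_fraction = report$test_fraction,
                      cv_folds = report$cv_folds,
                      cv_repeats = report$cv_repeats,
                      prob_threshold = report$prob_threshold,
                      split_unit = report$split_unit,
                      seed = report$seed))
  } else {
    x <- unclass(report)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
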