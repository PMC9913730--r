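#' Rolling-window minimum/maximum features
#'
#' For every defined calf-hour of the input series, computes the 20
#' trailing-window features used by the fever classifier: for each window
#' length k in `windows` (hours, current hour inclusive), the window minimum
#' `h{k}min`, the window maximum `h{k}max`, and the signed differences
#' between the current value and those extremes, `h{k}mindiff = v - h{k}min`
#' (>= 0) and `h{k}maxdiff = v - h{k}max` (<= 0). A row is emitted only
#' where the current value is defined and every window holds at least
#' `min_window_coverage` of its k slots.
#'
#' @param rst an `hourly_series`; the classifier uses the estimated rST, but
#'   any role is accepted (a config switch at the pipeline level selects the
#'   input series).
#' @param windows trailing window lengths in hours.
#' @param min_window_coverage minimum fraction of window slots present.
#' @return a `feature_table`: data.frame `calf_id`, `hour`, then 4 features
#'   per window, with attributes `feature_names` and `windows`.
#' @export
extract_features <- function(rst, windows = c(3, 6, 12, 24, 48),
                             min_window_coverage = 0.5) {
  stopifnot(all(windows >= 1), !anyDuplicated(windows))
  windows <- as.integer(sort(windows))
  feat_names <- as.vector(vapply(windows, function(k) {
    sprintf("h%d%s", k, c("min", "max", "mindiff", "maxdiff"))
  }, character(4)))

  parts <- lapply(split(seq_len(nrow(rst)), rst$calf_id), function(idx) {
    g <- hourly_grid(rst$hour[idx], rst$value[idx])
    v <- g$value
    cols <- vector("list", length(feat_names))
    names(cols) <- feat_names
    ok <- !is.na(v)
    for (k in windows) {
      r <- roll_trailing(v, k)
      ok <- ok & (r$n / k >= min_window_coverage)
      cols[[sprintf("h%dmin", k)]] <- r$min
      cols[[sprintf("h%dmax", k)]] <- r$max
      cols[[sprintf("h%dmindiff", k)]] <- v - r$min
      cols[[sprintf("h%dmaxdiff", k)]] <- v - r$max
    }
    out <- data.frame(calf_id = rst$calf_id[idx[1L]], hour = g$hour,
                      stringsAsFactors = FALSE)
    for (nm in feat_names) out[[nm]] <- cols[[nm]]
    out[ok, , drop = FALSE]
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$calf_id, out$hour), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, feature_names = feat_names, windows = windows,
            class = c("feature_table", "data.frame"))
}

#' Feature-column names of a feature table
#' @param table a `feature_table`.
#' @return character vector of predictor column names.
#' @export
feature_names <- function(table) attr(table, "feature_names")

one_hot <- function(values, prefix, levels) {
  cols <- lapply(levels, function(l) as.integer(values == l))
  names(cols) <- paste0(prefix, "_", gsub("[^[:alnum:]]+", "_", levels))
  cols
}

#' Attach fever labels and optional arrival metadata to a feature table
#'
#' Joins the hourly 0/1 fever label by (calf, hour); feature rows whose hour
#' has no defined label are dropped (a message reports how many). With
#' `use_metadata = TRUE` the six arrival covariates are joined by calf:
#' numeric covariates pass through, categorical ones (sex, season at
#' introduction, blood line) are expanded into one-hot indicator columns
#' (no reference level dropped - tree models need none).
#'
#' @param table a `feature_table` from [extract_features()].
#' @param labels data.frame from [label_fever()].
#' @param metadata per-calf metadata data.frame (see [simulate_calves()]);
#'   required when `use_metadata = TRUE`.
#' @param use_metadata logical.
#' @return the labeled `feature_table` with a `label` column (and metadata
#'   feature columns when requested); `feature_names` updated.
#' @export
attach_labels_and_metadata <- function(table, labels, metadata = NULL,
                                       use_metadata = FALSE) {
  key <- function(id, hr) paste(id, hour_index(hr))
  lab <- labels$label[match(key(table$calf_id, table$hour),
                            key(labels$calf_id, labels$hour))]
  drop_n <- sum(is.na(lab))
  if (drop_n > 0) {
    message(drop_n, " feature row(s) without a defined label dropped")
  }
  out <- table[!is.na(lab), , drop = FALSE]
  out$label <- as.integer(lab[!is.na(lab)])
  fnames <- feature_names(table)

  if (use_metadata) {
    if (is.null(metadata)) stop("use_metadata = TRUE but no metadata given")
    miss <- setdiff(unique(out$calf_id), metadata$calf_id)
    if (length(miss)) {
      stop("calf absent from metadata: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    m <- metadata[match(out$calf_id, metadata$calf_id), , drop = FALSE]
    for (nm in c("arrival_age_days", "arrival_weight_kg",
                 "chest_circumference_cm")) {
      out[[nm]] <- m[[nm]]
      fnames <- c(fnames, nm)
    }
    cat_cols <- list(sex = .sexes, season_at_introduction = .seasons,
                     blood_line = .blood_lines)
    for (nm in names(cat_cols)) {
      lv <- sort(unique(c(cat_cols[[nm]], m[[nm]])))
      oh <- one_hot(m[[nm]], nm, lv)
      for (cn in names(oh)) out[[cn]] <- oh[[cn]]
      fnames <- c(fnames, names(oh))
    }
  }
  rownames(out) <- NULL
  structure(out, feature_names = fnames, windows = attr(table, "windows"),
            class = c("feature_table", "data.frame"))
}
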