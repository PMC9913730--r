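# Shared fixture builders and independent brute-force oracles.

t0 <- as.POSIXct("2023-04-01 00:00:00", tz = "UTC")

# hourly_series from a numeric vector; NA entries become absent hours
mk_hourly <- function(values, calf = "A", role = "estimated_rst",
                      start = t0) {
  hours <- start + 3600 * (seq_along(values) - 1)
  def <- !is.na(values)
  structure(
    data.frame(calf_id = rep(calf, sum(def)), hour = hours[def],
               value = values[def], stringsAsFactors = FALSE),
    value_role = role, class = c("hourly_series", "data.frame"))
}

mk_traces <- function(temps, calf = "A", start = t0, by_min = 10) {
  data.frame(calf_id = rep(calf, length(temps)),
             timestamp = start + 60 * by_min * (seq_along(temps) - 1),
             temp_c = temps, stringsAsFactors = FALSE)
}

# Brute-force fever labeling oracle: an hour is 1 iff it belongs to some
# window of `run` consecutive grid hours that are all defined and >= thr.
brute_labels <- function(values, thr, run) {
  n <- length(values)
  lab <- integer(n)
  qual <- !is.na(values) & values >= thr
  if (n >= run) {
    for (i in 1:(n - run + 1)) {
      if (all(qual[i:(i + run - 1)])) lab[i:(i + run - 1)] <- 1L
    }
  }
  lab[is.na(values)] <- NA_integer_
  lab
}

# Brute-force rolling-feature oracle: re-scan every trailing window.
brute_features <- function(values, windows = c(3, 6, 12, 24, 48),
                           min_cov = 0.5) {
  n <- length(values)
  rows <- list()
  for (t in seq_len(n)) {
    v <- values[t]
    if (is.na(v)) next
    feats <- list()
    ok <- TRUE
    for (k in windows) {
      w <- values[max(1, t - k + 1):t]
      pres <- sum(!is.na(w))
      if (pres / k < min_cov) { ok <- FALSE; break }
      mn <- min(w, na.rm = TRUE); mx <- max(w, na.rm = TRUE)
      feats[[sprintf("h%dmin", k)]] <- mn
      feats[[sprintf("h%dmax", k)]] <- mx
      feats[[sprintf("h%dmindiff", k)]] <- v - mn
      feats[[sprintf("h%dmaxdiff", k)]] <- v - mx
    }
    if (ok) rows[[length(rows) + 1]] <- c(list(pos = t), feats)
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

# labeled feature table where label = 1{h3min >= 1}: separable by design
toy_feature_table <- function(n_hours = 600, seed = 99, calf = "T1") {
  set.seed(seed)
  vals <- stats::rnorm(n_hours, 0.9, 0.6)
  ft <- extract_features(mk_hourly(vals, calf = calf))
  labs <- data.frame(calf_id = ft$calf_id, hour = ft$hour,
                     label = as.integer(ft$h3min >= 1.0))
  attach_labels_and_metadata(ft, labs)
}

# quiet config for fast end-to-end runs; episode rate raised so the small
# cohort always carries both classes
mini_config <- function(seed = 7, ...) {
  pipeline_config(sim = sim_config(n_calves = 4, duration_days = 8,
                                   fever_episode_rate = 4, seed = seed, ...),
                  cv_repeats = 1, seed = seed)
}
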