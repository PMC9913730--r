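#' Rhythm-corrected estimated surface temperature
#'
#' Point formula mapping a raw surface temperature (ST) reading and the
#' trailing-24-h extremes onto a rhythm-corrected estimate:
#'
#' \deqn{Est = Tem + (Max_{24h} - Tem) \times
#'   \frac{Max_{24h} - Min_{24h} - 0.9}{Max_{24h} - Min_{24h}}}
#'
#' The 0.9 degC constant is the reference daily ST range established in prior
#' experimental-infection work on Holstein-Friesian calves; when the observed
#' 24-h range exceeds it the estimate moves toward the 24-h maximum, and when
#' the range falls below it the estimate is pushed below the current value.
#' A degenerate window (`max_24h == min_24h`) carries no rhythm to correct
#' and returns `tem` unchanged.
#'
#' @param tem current raw ST value, degC.
#' @param max_24h,min_24h extremes of ST over the trailing 24 h (current
#'   value included), degC.
#' @return the estimated ST, degC (vectorized).
#' @examples
#' estimated_st(38.0, 39.0, 37.0)  # 38.55
#' @export
estimated_st <- function(tem, max_24h, min_24h) {
  rng <- max_24h - min_24h
  out <- ifelse(rng == 0, tem, tem + (max_24h - tem) * ((rng - 0.9) / rng))
  out[is.na(tem) | is.na(max_24h) | is.na(min_24h)] <- NA_real_
  out
}

# apply estimated_st along one calf's contiguous hourly vector
estimate_series_vec <- function(x, min_coverage) {
  r <- roll_trailing(x, 24L)
  est <- estimated_st(x, r$max, r$min)
  est[r$n / 24 < min_coverage] <- NA_real_
  est[is.na(x)] <- NA_real_
  est
}

# same-clock-time baseline subtraction along one contiguous hourly vector
residual_series_vec <- function(x, lookback_days, min_baseline_days) {
  n <- length(x)
  lagged <- lapply(seq_len(lookback_days), function(d) {
    j <- d * 24L
    c(rep(NA_real_, min(j, n)), x[seq_len(max(0L, n - j))])
  })
  cnt <- Reduce(`+`, lapply(lagged, function(v) as.integer(!is.na(v))))
  total <- Reduce(`+`, lapply(lagged, function(v) ifelse(is.na(v), 0, v)))
  base <- ifelse(cnt >= min_baseline_days, total / cnt, NA_real_)
  x - base
}

# run f over each calf's gridded hourly values, return hourly data.frame
map_hourly <- function(hourly, f) {
  parts <- lapply(split(seq_len(nrow(hourly)), hourly$calf_id), function(idx) {
    g <- hourly_grid(hourly$hour[idx], hourly$value[idx])
    val <- f(g$value)
    def <- !is.na(val)
    data.frame(calf_id = rep(hourly$calf_id[idx[1L]], sum(def)),
               hour = g$hour[def], value = val[def], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out[order(out$calf_id, out$hour), , drop = FALSE]
}

#' Estimated ST over an hourly series
#'
#' Applies [estimated_st()] at every hour, with the 24-h extremes taken over
#' the trailing 24 hourly values (current hour inclusive). Hours whose
#' window holds fewer than `min_coverage` of its 24 slots, or whose own value
#' is absent, are undefined and dropped from the output.
#'
#' @param hourly an `hourly_series` (see [hourly_max()]).
#' @param min_coverage minimum fraction of the 24 hourly window slots that
#'   must be present (default 0.5, i.e. >= 12 values).
#' @return an `hourly_series` with `value_role = "estimated_st"`.
#' @export
st_estimate <- function(hourly, min_coverage = 0.5) {
  out <- map_hourly(hourly, function(x) estimate_series_vec(x, min_coverage))
  new_hourly(out, "estimated_st")
}

#' Residual surface temperature (same-time baseline subtraction)
#'
#' Subtracts, at each hour, the mean value at the same clock time over the
#' previous `lookback_days` days. This removes the diurnal rhythm and the
#' calf's individual baseline, leaving the residual ST (rST) - the elevation
#' over the calf's own recent same-time behaviour. Hours with fewer than
#' `min_baseline_days` same-time values available are undefined; by
#' construction the first `lookback_days` days of a series are largely
#' undefined.
#'
#' @param hourly an `hourly_series` of raw hourly maxima or estimated ST.
#' @param lookback_days number of previous days in the baseline (default 3).
#' @param min_baseline_days minimum number of same-time values required
#'   (default 2 of 3, robust to dropouts).
#' @return an `hourly_series` with `value_role = "rst"` (input raw) or
#'   `"estimated_rst"` (input estimated ST).
#' @export
residual_st <- function(hourly, lookback_days = 3, min_baseline_days = 2) {
  stopifnot(lookback_days >= 1, min_baseline_days >= 1,
            min_baseline_days <= lookback_days)
  out <- map_hourly(hourly, function(x) {
    residual_series_vec(x, lookback_days, min_baseline_days)
  })
  role <- if (identical(value_role(hourly), "estimated_st")) {
    "estimated_rst"
  } else {
    "rst"
  }
  new_hourly(out, role)
}

#' All four hourly surface-temperature measurements
#'
#' From a raw hourly-maximum series computes the four measurements used
#' throughout the analysis: raw hourly ST, estimated ST ([st_estimate()]),
#' rST (residual of raw), and estimated rST (residual of estimated ST -
#' estimate first, then residualize).
#'
#' @inheritParams st_estimate
#' @inheritParams residual_st
#' @return data.frame `calf_id`, `hour`, `raw`, `estimated_st`, `rst`,
#'   `estimated_rst`; `NA` marks undefined values.
#' @export
st_transforms <- function(hourly, min_coverage = 0.5, lookback_days = 3,
                          min_baseline_days = 2) {
  est <- st_estimate(hourly, min_coverage)
  rst <- residual_st(hourly, lookback_days, min_baseline_days)
  erst <- residual_st(est, lookback_days, min_baseline_days)

  key <- function(df) paste(df$calf_id, hour_index(df$hour))
  out <- data.frame(calf_id = hourly$calf_id, hour = hourly$hour,
                    raw = hourly$value, stringsAsFactors = FALSE)
  k <- key(out)
  out$estimated_st <- est$value[match(k, key(est))]
  out$rst <- rst$value[match(k, key(rst))]
  out$estimated_rst <- erst$value[match(k, key(erst))]
  out[order(out$calf_id, out$hour), , drop = FALSE]
}

# pull one measurement column of st_transforms() output back into an
# hourly_series with the right role tag
measurement_series <- function(transforms, measurement) {
  stopifnot(measurement %in% c("raw", "estimated_st", "rst", "estimated_rst"))
  def <- !is.na(transforms[[measurement]])
  role <- if (measurement == "raw") "raw_hourly_max" else measurement
  new_hourly(data.frame(calf_id = transforms$calf_id[def],
                        hour = transforms$hour[def],
                        value = transforms[[measurement]][def],
                        stringsAsFactors = FALSE), role)
}
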