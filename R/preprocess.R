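#' Remove physiologically implausible extreme readings
#'
#' Drops records at or beyond the plausibility bounds: `temp_c <= low` or
#' `temp_c >= high` (bounds inclusive). All other records are preserved in
#' time order.
#'
#' @param traces data.frame `calf_id`, `timestamp`, `temp_c`.
#' @param low,high exclusion bounds in degC; readings `<= low` or `>= high`
#'   are removed.
#' @return the filtered data.frame; may be empty.
#' @export
filter_extremes <- function(traces, low = 30, high = 45) {
  stopifnot(low < high)
  out <- traces[traces$temp_c > low & traces$temp_c < high, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# sequential comparator scan for one calf's temperatures
jump_keep <- function(x, max_step) {
  n <- length(x)
  keep <- logical(n)
  if (n == 0L) return(keep)
  keep[1L] <- TRUE
  last <- x[1L]
  if (n >= 2L) {
    for (i in 2:n) {
      if (abs(x[i] - last) < max_step) {
        keep[i] <- TRUE
        last <- x[i]
      }
    }
  }
  keep
}

#' Remove records implicated in abrupt jumps
#'
#' Scanning each calf's records in time order, a record whose absolute
#' difference from the last *retained* record is `>= max_step` is removed;
#' the retained record stays the comparator for subsequent records. The later
#' record of an offending pair is always the one removed, so an isolated
#' spike does not delete its valid neighbours, and a sustained step artifact
#' is treated as invalid until the signal returns near the retained level.
#' The scan is idempotent: a second pass changes nothing.
#'
#' @param traces data.frame `calf_id`, `timestamp`, `temp_c`; extremes should
#'   already be filtered.
#' @param max_step exclusion threshold in degC; `|delta| >= max_step` is a jump.
#' @return the filtered data.frame.
#' @export
filter_jumps <- function(traces, max_step = 1.0) {
  stopifnot(max_step > 0)
  if (nrow(traces) == 0L) return(traces)
  keep <- unlist(lapply(split(traces$temp_c, traces$calf_id),
                        jump_keep, max_step = max_step), use.names = FALSE)
  # split() orders groups by factor level; realign to the original row order
  ord <- order(match(traces$calf_id, sort(unique(traces$calf_id))))
  out <- traces[ord, , drop = FALSE][keep, , drop = FALSE]
  out <- out[order(out$calf_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_hourly <- function(df, role) {
  rownames(df) <- NULL
  structure(df, value_role = role, class = c("hourly_series", "data.frame"))
}

#' Hourly value role
#'
#' @param x an hourly series produced by [hourly_max()], [st_estimate()] or
#'   [residual_st()].
#' @return the role tag: one of `"raw_hourly_max"`, `"estimated_st"`,
#'   `"rst"`, `"estimated_rst"`.
#' @export
value_role <- function(x) attr(x, "value_role")

#' Extract the hourly maximum surface temperature
#'
#' For each calf and clock hour with at least one record, returns the maximum
#' temperature over `[hour, hour + 1)`. Taking the hourly maximum damps the
#' effect of transient dips in the raw 10-minute signal. Hours without
#' records are absent from the output.
#'
#' @param traces filtered data.frame `calf_id`, `timestamp`, `temp_c`.
#' @return an `hourly_series` data.frame `calf_id`, `hour`, `value` with
#'   `value_role = "raw_hourly_max"`.
#' @export
hourly_max <- function(traces) {
  if (nrow(traces) == 0L) {
    return(new_hourly(data.frame(calf_id = character(),
                                 hour = as_clock_time(numeric()),
                                 value = numeric(), stringsAsFactors = FALSE),
                      "raw_hourly_max"))
  }
  hr <- floor_hour(traces$timestamp)
  parts <- lapply(split(seq_len(nrow(traces)), traces$calf_id), function(idx) {
    mx <- tapply(traces$temp_c[idx], hour_index(hr[idx]), max)
    data.frame(calf_id = traces$calf_id[idx[1L]],
               hour = as_clock_time(as.numeric(names(mx)) * 3600),
               value = as.numeric(mx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$calf_id, out$hour), , drop = FALSE]
  new_hourly(out, "raw_hourly_max")
}

#' Full preprocessing pipeline: extremes, jumps, hourly maximum
#'
#' Applies the three cleaning rules in their fixed order: extreme-value
#' removal, jump removal, hourly-maximum extraction.
#'
#' @inheritParams filter_extremes
#' @inheritParams filter_jumps
#' @return an `hourly_series` with `value_role = "raw_hourly_max"`.
#' @export
preprocess_st <- function(traces, low = 30, high = 45, max_step = 1.0) {
  hourly_max(filter_jumps(filter_extremes(traces, low, high), max_step))
}
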