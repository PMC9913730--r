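#' Label fever hours from the estimated residual surface temperature
#'
#' Fever is defined as an elevation of at least `threshold` degC of the
#' estimated rST sustained over `run_length` consecutive hours. Every
#' maximal run of consecutive *defined* hours with value `>= threshold` and
#' length `>= run_length` has all of its hours labeled 1; all other defined
#' hours are labeled 0. An undefined hour (sensor gap) breaks a run. With
#' `confirmed_only = TRUE` only hours from position `run_length` of a
#' qualifying run onward are labeled 1 (the label switches on only once the
#' elevation is confirmed).
#'
#' @param rst an `hourly_series` with `value_role = "estimated_rst"` (or
#'   `"rst"`).
#' @param threshold elevation threshold, degC.
#' @param run_length required number of consecutive qualifying hours.
#' @param confirmed_only logical; see above.
#' @return data.frame `calf_id`, `hour`, `label` (integer 0/1) covering every
#'   defined hour of the input.
#' @export
label_fever <- function(rst, threshold = 1.0, run_length = 4,
                        confirmed_only = FALSE) {
  stopifnot(run_length >= 1, is.finite(threshold))
  parts <- lapply(split(seq_len(nrow(rst)), rst$calf_id), function(idx) {
    g <- hourly_grid(rst$hour[idx], rst$value[idx])
    lab <- label_runs_vec(g$value, threshold, run_length, confirmed_only)
    def <- !is.na(g$value)
    data.frame(calf_id = rst$calf_id[idx[1L]], hour = g$hour[def],
               label = lab[def], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$calf_id, out$hour), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# run labeling on one contiguous hourly vector (NA = undefined hour)
label_runs_vec <- function(x, threshold, run_length, confirmed_only = FALSE) {
  qual <- !is.na(x) & x >= threshold   # NA (gap) breaks runs
  r <- rle(qual)
  lab <- integer(length(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$lengths)) {
    if (r$values[j] && r$lengths[j] >= run_length) {
      from <- if (confirmed_only) starts[j] + run_length - 1L else starts[j]
      lab[from:ends[j]] <- 1L
    }
  }
  lab[is.na(x)] <- NA_integer_
  lab
}

#' Collapse hourly fever labels into episodes
#'
#' Maximal runs of consecutive hours labeled 1 become closed intervals
#' `[start, end]`, for episode-level reporting and comparison with
#' ground-truth episodes.
#'
#' @param labels data.frame `calf_id`, `hour`, `label` from [label_fever()].
#' @return data.frame `calf_id`, `start`, `end`, `n_hours`.
#' @export
episodes_from_labels <- function(labels) {
  parts <- lapply(split(seq_len(nrow(labels)), labels$calf_id), function(idx) {
    hrs <- hour_index(labels$hour[idx])
    pos <- hrs[labels$label[idx] == 1L]
    if (!length(pos)) return(NULL)
    pos <- sort(pos)
    brk <- c(TRUE, diff(pos) > 1L)
    grp <- cumsum(brk)
    data.frame(calf_id = labels$calf_id[idx[1L]],
               start = as_clock_time(tapply(pos, grp, min) * 3600),
               end = as_clock_time(tapply(pos, grp, max) * 3600),
               n_hours = as.integer(tapply(pos, grp, length)),
               stringsAsFactors = FALSE)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) {
    return(data.frame(calf_id = character(), start = as_clock_time(numeric()),
                      end = as_clock_time(numeric()), n_hours = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
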