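# Internal helpers shared across modules. All timestamps are timezone-naive
# farm-local clock time, represented as POSIXct in UTC so that arithmetic is
# DST-free and reproducible across machines.

.origin <- "1970-01-01"

as_clock_time <- function(x) {
  as.POSIXct(x, tz = "UTC", origin = .origin)
}

floor_hour <- function(ts) {
  as_clock_time(floor(as.numeric(ts) / 3600) * 3600)
}

# integer hour index since epoch; inputs are hour-aligned POSIXct
hour_index <- function(ts) {
  as.integer(round(as.numeric(ts) / 3600))
}

hour_of_day <- function(ts) {
  (as.numeric(ts) %% 86400) / 3600
}

# Trailing-window extrema over a vector laid out on a contiguous grid.
# Window for position i covers positions i-k+1 .. i (current inclusive).
# Returns list(min, max, n) where n counts non-NA values in the window.
roll_trailing <- function(x, k) {
  n <- length(x)
  shifts <- lapply(seq_len(k) - 1L, function(j) {
    if (j == 0L) x else c(rep(NA_real_, min(j, n)), x[seq_len(max(0L, n - j))])
  })
  cnt <- Reduce(`+`, lapply(shifts, function(v) as.integer(!is.na(v))))
  mins <- do.call(pmin, c(shifts, list(na.rm = TRUE)))
  maxs <- do.call(pmax, c(shifts, list(na.rm = TRUE)))
  mins[cnt == 0L] <- NA_real_
  maxs[cnt == 0L] <- NA_real_
  list(min = mins, max = maxs, n = cnt)
}

# Lay a single calf's hourly values onto a contiguous hourly grid spanning
# [min(hour), max(hour)]; absent hours become NA.
hourly_grid <- function(hours, values) {
  idx <- hour_index(hours)
  lo <- min(idx)
  grid_idx <- lo:max(idx)
  x <- rep(NA_real_, length(grid_idx))
  x[idx - lo + 1L] <- values
  list(index = grid_idx, value = x,
       hour = as_clock_time(as.numeric(grid_idx) * 3600))
}

# derive a per-stage seed from the global one, keeping it a valid 32-bit int
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
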