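#' Diurnal rhythm term of the simulated surface temperature
#'
#' Asymmetric cosine interpolation between the daily trough and peak: the
#' rhythm descends from peak to trough and ascends back along cosine
#' half-waves whose lengths match the trough-to-peak and peak-to-trough
#' intervals (11 h and 13 h at the default 06:00/17:00), reproducing the
#' asymmetric shape of the observed daily cycle rather than a pure sinusoid.
#'
#' @param hod clock hour of day, possibly fractional, in `[0, 24)`.
#' @param amplitude peak-to-trough amplitude, degC.
#' @param trough_hour,peak_hour clock hours of the daily minimum and maximum.
#' @return numeric vector of rhythm values in
#'   `[-amplitude/2, +amplitude/2]`; exactly `-amplitude/2` at
#'   `trough_hour` and `+amplitude/2` at `peak_hour`.
#' @export
diurnal_term <- function(hod, amplitude, trough_hour = 6, peak_hour = 17) {
  asc_len <- (peak_hour - trough_hour) %% 24
  desc_len <- 24 - asc_len
  h <- (hod - trough_hour) %% 24
  asc <- h <= asc_len
  val <- numeric(length(h))
  val[asc] <- -cos(pi * h[asc] / asc_len)
  val[!asc] <- cos(pi * (h[!asc] - asc_len) / desc_len)
  amplitude / 2 * val
}

# trapezoidal elevation profile of one episode, evaluated at times t (seconds)
episode_elevation <- function(t_sec, start_sec, end_sec, magnitude,
                              onset_ramp_h, offset_ramp_h) {
  up <- if (onset_ramp_h > 0) {
    (t_sec - start_sec) / (onset_ramp_h * 3600)
  } else {
    ifelse(t_sec >= start_sec, Inf, -Inf)
  }
  down <- if (offset_ramp_h > 0) {
    (end_sec - t_sec) / (offset_ramp_h * 3600)
  } else {
    ifelse(t_sec <= end_sec, Inf, -Inf)
  }
  magnitude * pmax(0, pmin(1, up, down))
}

# sum of all episode elevations for one calf at times t_sec
fever_signal <- function(t_sec, episodes, onset_ramp_h, offset_ramp_h) {
  elev <- numeric(length(t_sec))
  if (is.null(episodes) || nrow(episodes) == 0L) return(elev)
  for (i in seq_len(nrow(episodes))) {
    elev <- elev + episode_elevation(
      t_sec, as.numeric(episodes$start_time[i]),
      as.numeric(episodes$end_time[i]), episodes$magnitude_c[i],
      onset_ramp_h, offset_ramp_h)
  }
  elev
}

sim_start_time <- function() as_clock_time("2023-04-01 00:00:00")

.sexes <- c("male", "female")
.seasons <- c("spring", "summer", "autumn", "winter")
.blood_lines <- c("Tajiri", "Fujiyoshi", "Kedaka", "Itozakura")

simulate_metadata <- function(n_calves, calf_ids) {
  data.frame(
    calf_id = calf_ids,
    sex = sample(.sexes, n_calves, replace = TRUE),
    season_at_introduction = sample(.seasons, n_calves, replace = TRUE),
    arrival_age_days = round(stats::rnorm(n_calves, 105, 10)),
    arrival_weight_kg = round(stats::rnorm(n_calves, 110, 15), 1),
    chest_circumference_cm = round(stats::rnorm(n_calves, 116, 7), 1),
    blood_line = sample(.blood_lines, n_calves, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Episode-rate multiplier when the metadata effect is on: lighter calves at
# arrival and winter/autumn introductions run higher fever risk.
metadata_rate_factor <- function(meta) {
  w <- (110 - meta$arrival_weight_kg) / 15
  season_fac <- c(spring = 0.9, summer = 0.8, autumn = 1.1, winter = 1.3)
  exp(0.4 * w) * unname(season_fac[meta$season_at_introduction])
}

draw_episodes <- function(calf_id, n_ep, total_h, cfg) {
  if (n_ep == 0L) {
    return(data.frame(calf_id = character(), start_time = as_clock_time(numeric()),
                      end_time = as_clock_time(numeric()),
                      magnitude_c = numeric(), stringsAsFactors = FALSE))
  }
  start0 <- as.numeric(sim_start_time())
  starts <- numeric(0); ends <- numeric(0); mags <- numeric(0)
  for (i in seq_len(n_ep)) {
    dur_h <- stats::runif(1, cfg$fever_duration_range_h[1],
                          cfg$fever_duration_range_h[2])
    mag <- stats::runif(1, cfg$fever_magnitude_range_c[1],
                        cfg$fever_magnitude_range_c[2])
    if (dur_h >= total_h) next
    for (try in 1:20) {  # rejection sampling keeps episodes disjoint
      s <- start0 + stats::runif(1, 0, (total_h - dur_h)) * 3600
      e <- s + dur_h * 3600
      clear <- all(e < starts - 2 * 3600 | s > ends + 2 * 3600)
      if (clear) {
        starts <- c(starts, s); ends <- c(ends, e); mags <- c(mags, mag)
        break
      }
    }
  }
  o <- order(starts)
  data.frame(calf_id = rep(calf_id, length(starts)),
             start_time = as_clock_time(starts[o]),
             end_time = as_clock_time(ends[o]),
             magnitude_c = mags[o], stringsAsFactors = FALSE)
}

#' Simulate surface-temperature traces, fever episodes and calf metadata
#'
#' Generates, for each calf, a 10-minute surface-temperature (ST) record over
#' the configured duration as
#' baseline + diurnal rhythm + fever elevation + Gaussian noise,
#' then applies sensor artifacts: out-of-range spikes (values pushed outside
#' the 30-45 degC plausibility band), single-record step jumps of >= 1 degC,
#' and record dropouts. Fever episodes have a trapezoidal elevation profile
#' (linear onset/offset ramps around a plateau) and are returned as ground
#' truth together with arrival metadata. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `calf_sim`: a list with elements
#'   \describe{
#'     \item{traces}{data.frame `calf_id`, `timestamp`, `temp_c` on the
#'       10-minute grid (dropouts removed).}
#'     \item{episodes}{data.frame `calf_id`, `start_time`, `end_time`,
#'       `magnitude_c` of ground-truth fever episodes.}
#'     \item{metadata}{data.frame with one row per calf: `sex`,
#'       `season_at_introduction`, `arrival_age_days`, `arrival_weight_kg`,
#'       `chest_circumference_cm`, `blood_line`.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulate_calves(sim_config(n_calves = 2, duration_days = 5, seed = 7))
#' head(sim$traces)
#' @export
simulate_calves <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- as.integer(cfg$n_calves)
  calf_ids <- sprintf("C%03d", seq_len(n))
  meta <- simulate_metadata(n, calf_ids)
  baselines <- stats::rnorm(n, cfg$baseline_mean_c, cfg$baseline_sd_c)
  calf_amp <- cfg$diurnal_amplitude_c *
    exp(stats::rnorm(n, 0, cfg$calf_amplitude_sd) - cfg$calf_amplitude_sd^2 / 2)

  total_h <- cfg$duration_days * 24
  rate <- cfg$fever_episode_rate * cfg$duration_days / 30
  rate_fac <- if (cfg$metadata_effect) metadata_rate_factor(meta) else rep(1, n)
  n_eps <- stats::rpois(n, rate * rate_fac)

  t_grid <- as.numeric(sim_start_time()) +
    seq(0, cfg$duration_days * 86400 - cfg$sample_interval_min * 60,
        by = cfg$sample_interval_min * 60)
  hod <- hour_of_day(as_clock_time(t_grid))
  # unit-amplitude rhythm shape in [-0.5, 0.5]; scaled per calf-day below
  shape <- diurnal_term(hod, 1, cfg$diurnal_trough_hour, cfg$diurnal_peak_hour)
  day_of <- floor((t_grid - t_grid[1L]) / 86400) + 1L
  n_days <- as.integer(cfg$duration_days)

  trace_list <- vector("list", n)
  episode_list <- vector("list", n)
  for (i in seq_len(n)) {
    eps <- draw_episodes(calf_ids[i], n_eps[i], total_h, cfg)
    episode_list[[i]] <- eps
    # day-to-day modulation of the surface rhythm (environment/behaviour):
    # lognormal amplitude factor (mean 1) and a level shift, per calf-day
    amp_day <- calf_amp[i] *
      exp(stats::rnorm(n_days, 0, cfg$day_amplitude_sd) -
            cfg$day_amplitude_sd^2 / 2)
    level_day <- stats::rnorm(n_days, 0, cfg$day_level_sd_c)
    # slow AR(1) drift on the daily grid, interpolated within days
    rho <- exp(-1 / cfg$drift_corr_days)
    s <- numeric(n_days + 1L)
    s[1L] <- stats::rnorm(1, 0, cfg$drift_sd_c)
    for (d in seq_len(n_days) + 1L) {
      s[d] <- rho * s[d - 1L] +
        stats::rnorm(1, 0, cfg$drift_sd_c * sqrt(1 - rho^2))
    }
    day_frac <- (t_grid - t_grid[1L]) / 86400 - (day_of - 1L)
    drift <- s[day_of] * (1 - day_frac) + s[day_of + 1L] * day_frac
    diurnal <- amp_day[day_of] * shape + level_day[day_of]
    temp <- baselines[i] + diurnal + drift +
      fever_signal(t_grid, eps, cfg$fever_onset_ramp_h, cfg$fever_offset_ramp_h) +
      stats::rnorm(length(t_grid), 0, cfg$measurement_noise_sd_c)

    m <- length(t_grid)
    spike <- stats::runif(m) < cfg$spike_prob
    if (any(spike)) {
      low_side <- stats::runif(sum(spike)) < 0.5
      spike_val <- ifelse(low_side, stats::runif(sum(spike), 20, 30),
                          stats::runif(sum(spike), 45, 50))
      temp[spike] <- spike_val
    }
    step <- stats::runif(m) < cfg$step_artifact_prob
    if (any(step)) {
      temp[step] <- temp[step] +
        sample(c(-1, 1), sum(step), replace = TRUE) *
          stats::runif(sum(step), 1.0, 2.5)
    }
    keep <- stats::runif(m) >= cfg$dropout_prob
    trace_list[[i]] <- data.frame(
      calf_id = rep(calf_ids[i], sum(keep)),
      timestamp = as_clock_time(t_grid[keep]),
      temp_c = temp[keep], stringsAsFactors = FALSE)
  }

  out <- list(traces = do.call(rbind, trace_list),
              episodes = do.call(rbind, episode_list),
              metadata = meta,
              config = cfg)
  rownames(out$traces) <- NULL
  rownames(out$episodes) <- NULL
  class(out) <- "calf_sim"
  out
}

#' @export
print.calf_sim <- function(x, ...) {
  cat(sprintf("Simulated ST dataset: %d calves, %d records, %d fever episodes\n",
              nrow(x$metadata), nrow(x$traces), nrow(x$episodes)))
  invisible(x)
}

#' Simulate twice-daily rectal temperature measurements
#'
#' Two measurements per calf-day at times drawn uniformly within the farm's
#' measurement windows 08:00-09:00 and 16:00-17:00. The rectal value follows
#' the calf's core trajectory: population surface baseline plus the
#' core-minus-surface offset, the full fever elevation, an attenuated diurnal
#' term (factor 0.15 - the core circadian rhythm is a small fraction of the
#' feeding- and environment-driven skin rhythm), and
#' thermometer noise. The per-calf surface baseline deviation is treated as a
#' sensor-site effect and does not enter the core trajectory.
#'
#' @param config a [sim_config()] object.
#' @param traces simulated ST records (defines calves and the time span).
#' @param episodes ground-truth fever episodes from [simulate_calves()].
#' @return data.frame `calf_id`, `timestamp`, `rectal_temp_c`.
#' @export
simulate_rectal <- function(config, traces, episodes) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(derive_seed(cfg$seed, 10007))
  calves <- unique(traces$calf_id)
  day0 <- as.numeric(floor_hour(min(traces$timestamp)))
  day0 <- day0 - (day0 %% 86400)
  n_days <- as.integer(ceiling((as.numeric(max(traces$timestamp)) - day0) / 86400))

  rows <- vector("list", length(calves))
  diurnal_atten <- 0.15
  for (i in seq_along(calves)) {
    id <- calves[i]
    eps <- episodes[episodes$calf_id == id, , drop = FALSE]
    days <- day0 + (seq_len(n_days) - 1L) * 86400
    t_am <- days + (8 + stats::runif(n_days)) * 3600
    t_pm <- days + (16 + stats::runif(n_days)) * 3600
    t_all <- sort(c(t_am, t_pm))
    core <- cfg$baseline_mean_c + cfg$rectal_offset_mean_c +
      fever_signal(t_all, eps, cfg$fever_onset_ramp_h, cfg$fever_offset_ramp_h) +
      diurnal_atten * diurnal_term(hour_of_day(as_clock_time(t_all)),
                                   cfg$diurnal_amplitude_c,
                                   cfg$diurnal_trough_hour,
                                   cfg$diurnal_peak_hour) +
      stats::rnorm(length(t_all), 0, cfg$rectal_noise_sd_c)
    rows[[i]] <- data.frame(calf_id = rep(id, length(t_all)),
                            timestamp = as_clock_time(t_all),
                            rectal_temp_c = core, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
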