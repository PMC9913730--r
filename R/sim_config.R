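#' Simulation configuration for synthetic calf surface-temperature traces
#'
#' Builds and validates the configuration object consumed by
#' [simulate_calves()] and [simulate_rectal()]. Defaults describe the headline
#' study conditions: 120 calves monitored for one month at 10-minute
#' resolution, a 1.0 degC peak-to-trough diurnal rhythm with its trough near
#' 06:00 and peak near 17:00 (the farm's feeding times), fever episodes of
#' 1.5-3.0 degC lasting 6-48 h at a rate of 1.5 episodes per calf-month, and
#' low rates of sensor artifacts (dropouts, out-of-range spikes, step jumps).
#'
#' @param n_calves number of calves (>= 1).
#' @param duration_days length of each trace in days (>= 4; the residual
#'   transform needs 3 prior days of baseline).
#' @param sample_interval_min sensor sampling interval in minutes.
#' @param baseline_mean_c,baseline_sd_c mean and between-calf standard
#'   deviation of the surface-temperature baseline, degC. The per-calf
#'   deviation models sensor attachment and coat differences.
#' @param diurnal_amplitude_c peak-to-trough amplitude of the diurnal
#'   rhythm, degC.
#' @param diurnal_trough_hour,diurnal_peak_hour clock hours of the daily
#'   trough and peak.
#' @param calf_amplitude_sd log-scale standard deviation of the per-calf
#'   multiplicative factor on the diurnal amplitude: coat and attachment-site
#'   differences make the magnitude of the skin rhythm vary between calves.
#'   Standardizing this heterogeneity to a common reference band is the
#'   purpose of the estimated-ST transform.
#' @param day_amplitude_sd log-scale standard deviation of the per-calf-day
#'   multiplicative factor on the diurnal amplitude. The surface rhythm is
#'   feeding- and environment-driven, so its swing varies from day to day;
#'   this variability is what the range-normalizing estimated-ST transform
#'   corrects for. Set to 0 for a perfectly stable rhythm.
#' @param day_level_sd_c standard deviation (degC) of a per-calf-day level
#'   shift of the surface signal (weather and behaviour move skin
#'   temperature without moving core temperature).
#' @param drift_sd_c stationary standard deviation (degC) of a slow,
#'   multi-day autoregressive drift of the surface signal per calf -
#'   warm/cold spells and gradual changes at the attachment site. Absent
#'   from the core trajectory; the same-time baseline subtraction removes
#'   most of it, raw ST keeps all of it.
#' @param drift_corr_days correlation time of the slow drift, days.
#' @param fever_episode_rate expected fever episodes per calf per 30 days.
#' @param fever_magnitude_range_c length-2 numeric, degC plateau elevation of
#'   an episode drawn uniformly from this interval.
#' @param fever_duration_range_h length-2 numeric, episode duration in hours.
#' @param fever_onset_ramp_h,fever_offset_ramp_h linear ramp lengths, hours.
#' @param dropout_prob per-record probability that the record is lost.
#' @param spike_prob per-record probability of an out-of-range spike
#'   (value pushed below 30 or above 45 degC).
#' @param step_artifact_prob per-record probability of a single-record jump of
#'   at least 1 degC.
#' @param rectal_offset_mean_c mean core (rectal) minus surface baseline, degC.
#' @param rectal_noise_sd_c measurement noise of the rectal thermometer, degC.
#' @param measurement_noise_sd_c Gaussian sensor noise, degC.
#' @param metadata_effect logical; if `TRUE` the episode rate depends on
#'   arrival weight and season so metadata features carry signal.
#' @param seed integer seed making all simulator output reproducible.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [simulate_calves()], [simulate_rectal()]
#' @export
sim_config <- function(n_calves = 120,
                       duration_days = 30,
                       sample_interval_min = 10,
                       baseline_mean_c = 37.8,
                       baseline_sd_c = 0.7,
                       diurnal_amplitude_c = 1.0,
                       diurnal_trough_hour = 6,
                       diurnal_peak_hour = 17,
                       calf_amplitude_sd = 0.3,
                       day_amplitude_sd = 0.15,
                       day_level_sd_c = 0.1,
                       drift_sd_c = 0.7,
                       drift_corr_days = 7,
                       fever_episode_rate = 1.5,
                       fever_magnitude_range_c = c(1.5, 3.0),
                       fever_duration_range_h = c(6, 48),
                       fever_onset_ramp_h = 3,
                       fever_offset_ramp_h = 3,
                       dropout_prob = 0.01,
                       spike_prob = 0.002,
                       step_artifact_prob = 0.002,
                       rectal_offset_mean_c = 0.8,
                       rectal_noise_sd_c = 0.15,
                       measurement_noise_sd_c = 0.15,
                       metadata_effect = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_calves = n_calves, duration_days = duration_days,
    sample_interval_min = sample_interval_min,
    baseline_mean_c = baseline_mean_c, baseline_sd_c = baseline_sd_c,
    diurnal_amplitude_c = diurnal_amplitude_c,
    diurnal_trough_hour = diurnal_trough_hour,
    diurnal_peak_hour = diurnal_peak_hour,
    calf_amplitude_sd = calf_amplitude_sd,
    day_amplitude_sd = day_amplitude_sd,
    day_level_sd_c = day_level_sd_c,
    drift_sd_c = drift_sd_c,
    drift_corr_days = drift_corr_days,
    fever_episode_rate = fever_episode_rate,
    fever_magnitude_range_c = fever_magnitude_range_c,
    fever_duration_range_h = fever_duration_range_h,
    fever_onset_ramp_h = fever_onset_ramp_h,
    fever_offset_ramp_h = fever_offset_ramp_h,
    dropout_prob = dropout_prob, spike_prob = spike_prob,
    step_artifact_prob = step_artifact_prob,
    rectal_offset_mean_c = rectal_offset_mean_c,
    rectal_noise_sd_c = rectal_noise_sd_c,
    measurement_noise_sd_c = measurement_noise_sd_c,
    metadata_effect = isTRUE(metadata_effect),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid simulation configuration: field '", field, "' ", why,
         call. = FALSE)
  }
  num1 <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      fail(field, "must be a single finite number")
    }
    v
  }
  if (num1("n_calves") < 1) fail("n_calves", "must be >= 1")
  if (num1("duration_days") < 4) {
    fail("duration_days",
         "must be >= 4 (the residual transform needs 3 prior days)")
  }
  if (num1("sample_interval_min") <= 0) {
    fail("sample_interval_min", "must be positive")
  }
  if (num1("baseline_sd_c") < 0) fail("baseline_sd_c", "must be >= 0")
  if (num1("diurnal_amplitude_c") < 0) {
    fail("diurnal_amplitude_c", "must be >= 0")
  }
  for (f in c("diurnal_trough_hour", "diurnal_peak_hour")) {
    if (num1(f) < 0 || cfg[[f]] >= 24) fail(f, "must lie in [0, 24)")
  }
  if (cfg$diurnal_trough_hour == cfg$diurnal_peak_hour) {
    fail("diurnal_peak_hour", "must differ from diurnal_trough_hour")
  }
  if (num1("calf_amplitude_sd") < 0) fail("calf_amplitude_sd", "must be >= 0")
  if (num1("day_amplitude_sd") < 0) fail("day_amplitude_sd", "must be >= 0")
  if (num1("day_level_sd_c") < 0) fail("day_level_sd_c", "must be >= 0")
  if (num1("drift_sd_c") < 0) fail("drift_sd_c", "must be >= 0")
  if (num1("drift_corr_days") <= 0) fail("drift_corr_days", "must be > 0")
  if (num1("fever_episode_rate") < 0) fail("fever_episode_rate", "must be >= 0")
  for (f in c("fever_magnitude_range_c", "fever_duration_range_h")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)) ||
        v[1] > v[2] || v[1] <= 0) {
      fail(f, "must be a positive interval c(low, high) with low <= high")
    }
  }
  for (f in c("fever_onset_ramp_h", "fever_offset_ramp_h")) {
    if (num1(f) < 0) fail(f, "must be >= 0")
  }
  for (f in c("dropout_prob", "spike_prob", "step_artifact_prob")) {
    if (num1(f) < 0 || cfg[[f]] > 1) fail(f, "must lie in [0, 1]")
  }
  for (f in c("rectal_noise_sd_c", "measurement_noise_sd_c")) {
    if (num1(f) < 0) fail(f, "must be >= 0")
  }
  num1("rectal_offset_mean_c")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed)) {
    fail("seed", "must be a single integer")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Surface-temperature simulation configuration\n")
  cat(sprintf("  %d calves x %g days @ %g-min sampling (seed %d)\n",
              x$n_calves, x$duration_days, x$sample_interval_min, x$seed))
  cat(sprintf("  baseline %.1f +/- %.2f degC, diurnal %.1f degC (trough %02d:00, peak %02d:00)\n",
              x$baseline_mean_c, x$baseline_sd_c, x$diurnal_amplitude_c,
              as.integer(x$diurnal_trough_hour), as.integer(x$diurnal_peak_hour)))
  cat(sprintf("  fever: %.2g episodes/calf-month, +%.1f-%.1f degC for %g-%g h\n",
              x$fever_episode_rate, x$fever_magnitude_range_c[1],
              x$fever_magnitude_range_c[2], x$fever_duration_range_h[1],
              x$fever_duration_range_h[2]))
  cat(sprintf("  artifacts: dropout %.3g, spike %.3g, step %.3g; metadata effect: %s\n",
              x$dropout_prob, x$spike_prob, x$step_artifact_prob,
              x$metadata_effect))
  invisible(x)
}

#' Read or write a simulation configuration as YAML
#'
#' @param path file path.
#' @return `read_sim_config()` returns a validated [sim_config()] object;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown simulation configuration field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(sim_config, vals)
}

#' @param config a [sim_config()] object.
#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
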