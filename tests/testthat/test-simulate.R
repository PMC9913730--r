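test_that("config validation names the offending field", {
  expect_error(sim_config(n_calves = 0), "n_calves")
  expect_error(sim_config(duration_days = 3), "duration_days")
  expect_error(sim_config(dropout_prob = 1.2), "dropout_prob")
  expect_error(sim_config(fever_magnitude_range_c = c(3, 1)),
               "fever_magnitude_range_c")
  expect_error(sim_config(diurnal_peak_hour = 6, diurnal_trough_hour = 6),
               "diurnal_peak_hour")
})

test_that("artifact-free traces have exactly 144 records per calf-day", {
  cfg <- sim_config(n_calves = 3, duration_days = 5, dropout_prob = 0,
                    spike_prob = 0, step_artifact_prob = 0, seed = 4)
  sim <- simulate_calves(cfg)
  counts <- table(sim$traces$calf_id)
  expect_equal(unname(c(counts)), rep(5 * 144, 3))
  expect_true(all(diff(as.numeric(sim$traces$timestamp)) %% 600 == 0))
})

test_that("same seed reproduces the simulation; different seed does not", {
  cfg <- sim_config(n_calves = 2, duration_days = 5, seed = 11)
  s1 <- simulate_calves(cfg)
  s2 <- simulate_calves(cfg)
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$episodes, s2$episodes)
  expect_identical(s1$metadata, s2$metadata)
  s3 <- simulate_calves(sim_config(n_calves = 2, duration_days = 5, seed = 12))
  expect_false(identical(s1$traces$temp_c, s3$traces$temp_c))
})

test_that("noise-free, episode-free rhythm peaks and troughs where configured", {
  cfg <- sim_config(n_calves = 2, duration_days = 6, fever_episode_rate = 0,
                    measurement_noise_sd_c = 0, baseline_sd_c = 0,
                    calf_amplitude_sd = 0, day_amplitude_sd = 0,
                    day_level_sd_c = 0, drift_sd_c = 0,
                    dropout_prob = 0, spike_prob = 0, step_artifact_prob = 0,
                    seed = 2)
  sim <- simulate_calves(cfg)
  tr <- sim$traces[sim$traces$calf_id == "C001", ]
  hod <- (as.numeric(tr$timestamp) %% 86400) / 3600
  hourly_mean <- tapply(tr$temp_c, floor(hod), mean)
  expect_equal(names(which.min(hourly_mean)), "6")
  expect_equal(names(which.max(hourly_mean)), "17")
  # peak-to-trough span matches the configured amplitude at the exact hours
  on_grid <- tapply(tr$temp_c, hod, mean)
  expect_equal(unname(on_grid["17"] - on_grid["6"]), 1.0, tolerance = 1e-10)
})

test_that("zero episode rate yields no episodes and no sustained estimated-rST elevation", {
  cfg <- sim_config(n_calves = 4, duration_days = 8, fever_episode_rate = 0,
                    day_amplitude_sd = 0, day_level_sd_c = 0, drift_sd_c = 0,
                    dropout_prob = 0, spike_prob = 0, step_artifact_prob = 0,
                    seed = 5)
  sim <- simulate_calves(cfg)
  expect_equal(nrow(sim$episodes), 0L)
  erst <- measurement_series(
    st_transforms(preprocess_st(sim$traces)), "estimated_rst")
  labels <- label_fever(erst)
  expect_equal(sum(labels$label), 0L)
})

test_that("every clean well-sustained episode is flagged by downstream labeling", {
  cfg <- sim_config(n_calves = 8, duration_days = 12,
                    fever_episode_rate = 3,
                    fever_magnitude_range_c = c(1.5, 3),
                    fever_duration_range_h = c(16, 48),
                    fever_onset_ramp_h = 2, fever_offset_ramp_h = 2,
                    measurement_noise_sd_c = 0, day_amplitude_sd = 0,
                    day_level_sd_c = 0, drift_sd_c = 0, dropout_prob = 0,
                    spike_prob = 0, step_artifact_prob = 0, seed = 21)
  sim <- simulate_calves(cfg)
  expect_gt(nrow(sim$episodes), 5)
  erst <- measurement_series(
    st_transforms(preprocess_st(sim$traces)), "estimated_rst")
  labels <- label_fever(erst)
  flagged <- episodes_from_labels(labels)
  # episodes starting after the residual baseline exists must be detected
  day4 <- t0 + 4 * 86400
  for (i in seq_len(nrow(sim$episodes))) {
    ep <- sim$episodes[i, ]
    if (ep$start_time < day4) next
    hit <- flagged[flagged$calf_id == ep$calf_id &
                     flagged$end >= ep$start_time &
                     flagged$start <= ep$end_time, ]
    expect_gt(nrow(hit), 0, label = paste("episode", i, "flagged"))
  }
})

test_that("rectal sampling gives two measurements per day inside the stated windows", {
  cfg <- sim_config(n_calves = 1, duration_days = 7, seed = 3)
  sim <- simulate_calves(cfg)
  rectal <- simulate_rectal(cfg, sim$traces, sim$episodes)
  expect_equal(nrow(rectal), 14L)
  hod <- (as.numeric(rectal$timestamp) %% 86400) / 3600
  expect_true(all((hod >= 8 & hod <= 9) | (hod >= 16 & hod <= 17)))
})

test_that("noise-free rectal value during a fever plateau carries the full magnitude", {
  cfg <- sim_config(n_calves = 1, duration_days = 6, fever_episode_rate = 0,
                    rectal_noise_sd_c = 0, seed = 8)
  sim <- simulate_calves(cfg)
  ep <- data.frame(calf_id = "C001",
                   start_time = t0 + 4 * 86400,
                   end_time = t0 + 4 * 86400 + 20 * 3600,
                   magnitude_c = 2.0, stringsAsFactors = FALSE)
  rectal <- simulate_rectal(cfg, sim$traces, ep)
  hod <- (as.numeric(rectal$timestamp) %% 86400) / 3600
  # compare day-5 am measurement (plateau) with another day at the same window
  in_fever <- rectal$timestamp > ep$start_time + 3 * 3600 &
    rectal$timestamp < ep$end_time - 3 * 3600 & hod < 12
  base <- !in_fever & hod < 12
  expect_true(any(in_fever))
  delta <- mean(rectal$rectal_temp_c[in_fever]) -
    mean(rectal$rectal_temp_c[base])
  # same-window comparisons differ only by the attenuated rhythm over <1 h
  expect_equal(delta, 2.0, tolerance = 0.08)
})

test_that("metadata has one row per calf with valid categories", {
  sim <- simulate_calves(sim_config(n_calves = 25, duration_days = 4, seed = 6))
  md <- sim$metadata
  expect_equal(nrow(md), 25L)
  expect_equal(anyDuplicated(md$calf_id), 0L)
  expect_true(all(md$sex %in% c("male", "female")))
  expect_true(all(md$season_at_introduction %in%
                    c("spring", "summer", "autumn", "winter")))
  expect_true(all(md$arrival_weight_kg > 40 & md$arrival_weight_kg < 200))
})
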