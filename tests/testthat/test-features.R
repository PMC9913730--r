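test_that("rolling features match hand-computed values", {
  # last 3 values [0.2, 0.9, 1.4]: h3min 0.2, h3max 1.4, diffs 1.2 / 0.0
  vals <- c(rep(0.5, 10), 0.2, 0.9, 1.4)
  ft <- extract_features(mk_hourly(vals), windows = c(3, 6, 12))
  row <- ft[ft$hour == t0 + 12 * 3600, ]
  expect_equal(row$h3min, 0.2)
  expect_equal(row$h3max, 1.4)
  expect_equal(row$h3mindiff, 1.2)
  expect_equal(row$h3maxdiff, 0.0)
})

test_that("a constant series gives equal extrema and zero diffs", {
  ft <- extract_features(mk_hourly(rep(0.7, 120)))
  expect_true(all(ft$h48min == 0.7 & ft$h48max == 0.7))
  diffs <- as.matrix(ft[, grep("diff$", names(ft))])
  expect_equal(max(abs(diffs)), 0)
})

test_that("features equal a brute-force re-scan on random gappy series", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(c(60:150, 500), 1)
    vals <- rnorm(n, 0.5, 0.8)
    vals[runif(n) < 0.1] <- NA
    ft <- extract_features(mk_hourly(vals))
    want <- brute_features(vals)
    expect_equal(nrow(ft), nrow(want))
    got_pos <- as.numeric(ft$hour - t0, units = "hours") + 1
    expect_equal(got_pos, want$pos)
    for (nm in feature_names(ft)) {
      expect_equal(ft[[nm]], want[[nm]], label = nm)
    }
  }
})

test_that("window extrema nest across window lengths", {
  set.seed(78)
  vals <- rnorm(400, 0, 1)
  vals[runif(400) < 0.05] <- NA
  ft <- extract_features(mk_hourly(vals))
  expect_true(all(ft$h3min >= ft$h6min & ft$h6min >= ft$h12min &
                    ft$h12min >= ft$h24min & ft$h24min >= ft$h48min))
  expect_true(all(ft$h3max <= ft$h6max & ft$h6max <= ft$h12max &
                    ft$h12max <= ft$h24max & ft$h24max <= ft$h48max))
  expect_true(all(ft$h3mindiff >= 0) && all(ft$h3maxdiff <= 0))
})

test_that("labels join by calf-hour and the plain table has exactly 20 features", {
  vals <- c(rep(0.2, 60), rep(1.5, 12), rep(0.2, 30))
  s <- mk_hourly(vals)
  ft <- extract_features(s)
  labs <- label_fever(s)
  out <- attach_labels_and_metadata(ft, labs)
  expect_equal(length(feature_names(out)), 20L)
  expect_setequal(names(out), c("calf_id", "hour", feature_names(out), "label"))
  # labeled hours are exactly the qualifying run
  lab_hours <- out$hour[out$label == 1L]
  expect_equal(length(lab_hours), 12L)
})

test_that("labeled rows well inside an episode have h3min at or above threshold", {
  vals <- c(rep(0.2, 60), rep(1.5, 12), rep(0.2, 30))
  s <- mk_hourly(vals)
  out <- attach_labels_and_metadata(extract_features(s), label_fever(s))
  inside <- out$label == 1L & out$hour >= t0 + (60 + 2) * 3600
  expect_true(any(inside))
  expect_true(all(out$h3min[inside] >= 1.0))
})

test_that("metadata join validates calves and one-hot encodes categories", {
  sim <- simulate_calves(sim_config(n_calves = 3, duration_days = 6, seed = 9))
  hourly <- preprocess_st(sim$traces)
  erst <- measurement_series(st_transforms(hourly), "estimated_rst")
  ft <- extract_features(erst)
  labs <- label_fever(erst)
  out <- attach_labels_and_metadata(ft, labs, sim$metadata,
                                    use_metadata = TRUE)
  fn <- feature_names(out)
  expect_true(all(c("arrival_weight_kg", "sex_male", "sex_female",
                    "season_at_introduction_winter") %in% fn))
  expect_true(length(fn) > 20)
  expect_false(anyNA(out[, fn]))

  bad_md <- sim$metadata[-1, ]
  expect_error(
    attach_labels_and_metadata(ft, labs, bad_md, use_metadata = TRUE),
    "C001")
})

test_that("all-zero labels keep every row with label 0", {
  s <- mk_hourly(rep(0.1, 100))
  out <- attach_labels_and_metadata(extract_features(s), label_fever(s))
  expect_true(all(out$label == 0L))
  expect_equal(nrow(out), nrow(extract_features(s)))
})
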