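test_that("record split partitions exactly and reproducibly", {
  tab <- toy_feature_table(125)
  n <- nrow(tab)
  sp <- split_features(tab, test_fraction = 0.2, seed = 5)
  expect_equal(nrow(sp$test), round(n * 0.2))
  expect_equal(nrow(sp$train) + nrow(sp$test), n)
  key <- function(d) paste(d$calf_id, d$hour)
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  sp2 <- split_features(tab, test_fraction = 0.2, seed = 5)
  expect_identical(sp$test$hour, sp2$test$hour)
  expect_error(split_features(tab[1:5, ], seed = 1), "fewer than 10")
})

test_that("calf-level split keeps calves intact", {
  sim <- simulate_calves(sim_config(n_calves = 6, duration_days = 6, seed = 13))
  erst <- measurement_series(st_transforms(preprocess_st(sim$traces)),
                             "estimated_rst")
  tab <- attach_labels_and_metadata(extract_features(erst), label_fever(erst))
  sp <- split_features(tab, split_unit = "calf", seed = 3)
  expect_length(intersect(unique(sp$train$calf_id),
                          unique(sp$test$calf_id)), 0)
  expect_setequal(c(unique(sp$train$calf_id), unique(sp$test$calf_id)),
                  unique(tab$calf_id))
})

test_that("confusion metrics follow their defining formulas; 0/0 is NA", {
  m <- confusion_metrics(9, 89, 1, 1)
  expect_equal(m$accuracy, 0.98)
  expect_equal(m$precision, 0.90)
  expect_equal(m$sensitivity, 0.90)
  expect_warning(expect_warning(m0 <- confusion_metrics(0, 10, 0, 0),
                                "precision"), "sensitivity")
  expect_true(is.na(m0$precision))
  expect_equal(m0$accuracy, 1.0)
})

test_that("the fitted forest separates a rule-labeled table and is deterministic", {
  tab <- toy_feature_table(400)
  expect_gt(sum(tab$label), 10)
  fit1 <- fever_rf(tab, cross_validate = FALSE, seed = 2)
  fit2 <- fever_rf(tab, cross_validate = FALSE, seed = 2)
  expect_identical(predict(fit1, fit1$test), predict(fit2, fit2$test))
  # training-set fit is essentially perfect on a separable rule
  train_rep <- evaluate_fever(fit1, fit1$train)
  expect_gte(train_rep$accuracy, 0.99)
  # importances: every feature finite, non-negative, h3min dominant
  expect_true(all(is.finite(fit1$importance)) && all(fit1$importance >= 0))
  expect_length(fit1$importance, 20)
  expect_equal(names(fit1$importance)[1], "h3min")
})

test_that("single-class training data raise an informative error", {
  tab <- toy_feature_table(200)
  tab$label <- 0L
  expect_error(fever_rf(tab, cross_validate = FALSE, seed = 1), "class 1")
})

test_that("repeated k-fold CV produces folds x repeats rows and sane means", {
  tab <- toy_feature_table(300)
  cv <- fever_rf_cv(tab, cv_folds = 5, cv_repeats = 2, n_trees = 50, seed = 4)
  expect_equal(nrow(cv$folds), 10L)
  expect_gte(cv$means["accuracy"], 0.95)
  # a fold with no positives leaves sensitivity NA but completes
  tab0 <- tab
  tab0$label[tab0$label == 1L][-1] <- 0L  # exactly one positive row
  cv0 <- fever_rf_cv(tab0, cv_folds = 5, cv_repeats = 1, n_trees = 20,
                     seed = 4)
  expect_equal(nrow(cv0$folds), 5L)
  expect_true(anyNA(cv0$folds$sensitivity))
})

test_that("evaluation applies the probability threshold and metric identities hold", {
  tab <- toy_feature_table(400)
  fit <- fever_rf(tab, cross_validate = FALSE, seed = 6)
  rep <- fit$report
  tot <- rep$tp + rep$tn + rep$fp + rep$fn
  expect_equal(tot, nrow(fit$test))
  expect_equal(rep$accuracy, (rep$tp + rep$tn) / tot)
  if (rep$tp + rep$fp > 0) {
    expect_equal(rep$precision, rep$tp / (rep$tp + rep$fp))
  }
  expect_equal(rep$sensitivity, rep$tp / (rep$tp + rep$fn))
  # prediction classes are thresholded probabilities
  prob <- predict(fit, fit$test, type = "prob")
  cls <- predict(fit, fit$test, type = "class")
  expect_equal(cls, as.integer(prob > 0.5))
  expect_error(evaluate_fever(fit, fit$test[0, ]), "empty")
})

test_that("an independent random-forest implementation agrees on the separable rule", {
  skip_if_not_installed("randomForest")
  tab <- toy_feature_table(400, seed = 101)
  fit <- fever_rf(tab, cross_validate = FALSE, seed = 8)
  set.seed(8)
  rf <- randomForest::randomForest(
    x = fit$train[, feature_names(tab)],
    y = factor(fit$train$label, levels = c(0, 1)), ntree = 100)
  alt_pred <- as.integer(
    predict(rf, fit$test[, feature_names(tab)], type = "prob")[, "1"] > 0.5)
  own_pred <- predict(fit, fit$test, type = "class")
  expect_gte(mean(alt_pred == own_pred), 0.97)
  expect_equal(names(sort(randomForest::importance(rf)[, 1],
                          decreasing = TRUE))[1], "h3min")
})
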