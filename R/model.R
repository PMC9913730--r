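# carry feature_table attributes through subsetting
ft_subset <- function(table, idx) {
  out <- table[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, feature_names = attr(table, "feature_names"),
            windows = attr(table, "windows"),
            class = c("feature_table", "data.frame"))
}

#' Split a labeled feature table into training and test sets
#'
#' Random, uniform, disjoint and exhaustive 80/20-style partition. The
#' default record-level split samples rows; `split_unit = "calf"` keeps every
#' calf's rows together (no calf appears in both partitions), which avoids
#' leaking within-calf autocorrelation across the split.
#'
#' @param table labeled `feature_table`.
#' @param test_fraction fraction held out (0 < f < 1).
#' @param split_unit `"record"` or `"calf"`.
#' @param seed integer seed for the partition.
#' @return list with elements `train` and `test`.
#' @export
split_features <- function(table, test_fraction = 0.2,
                           split_unit = c("record", "calf"), seed = 1L) {
  split_unit <- match.arg(split_unit)
  n <- nrow(table)
  if (n < 10L) stop("feature table has fewer than 10 rows", call. = FALSE)
  stopifnot(test_fraction > 0, test_fraction < 1)
  set.seed(as.integer(seed))
  if (split_unit == "record") {
    n_test <- round(n * test_fraction)
    test_idx <- sample.int(n, n_test)
  } else {
    calves <- unique(table$calf_id)
    n_test_calves <- max(1L, round(length(calves) * test_fraction))
    test_calves <- sample(calves, n_test_calves)
    test_idx <- which(table$calf_id %in% test_calves)
  }
  list(train = ft_subset(table, setdiff(seq_len(n), test_idx)),
       test = ft_subset(table, sort(test_idx)))
}

rf_fit <- function(train, n_trees, seed) {
  fnames <- feature_names(train)
  y <- factor(train$label, levels = c(0, 1))
  if (any(table(y) == 0L)) {
    miss <- levels(y)[table(y) == 0L]
    stop("training data contain no rows of class ", miss, call. = FALSE)
  }
  ranger::ranger(
    x = train[, fnames, drop = FALSE], y = y,
    num.trees = n_trees, probability = TRUE, importance = "impurity",
    seed = as.integer(seed), num.threads = 1L)
}

rf_prob <- function(forest, table) {
  fnames <- feature_names(table)
  p <- stats::predict(forest, data = table[, fnames, drop = FALSE],
                      num.threads = 1L)$predictions
  p[, "1"]
}

#' Confusion-count metrics: accuracy, precision, sensitivity
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)` and
#' sensitivity `TP/(TP+FN)`. A 0/0 ratio is undefined and reported as `NA`
#' with a warning, never as 0 or 1.
#'
#' @param tp,tn,fp,fn confusion counts.
#' @return named list `tp`, `tn`, `fp`, `fn`, `accuracy`, `precision`,
#'   `sensitivity`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (0/0); reported as NA", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       accuracy = safe_div(tp + tn, total, "accuracy"),
       precision = safe_div(tp, tp + fp, "precision"),
       sensitivity = safe_div(tp, tp + fn, "sensitivity"))
}

eval_counts <- function(pred, truth) {
  list(tp = sum(pred == 1L & truth == 1L), tn = sum(pred == 0L & truth == 0L),
       fp = sum(pred == 1L & truth == 0L), fn = sum(pred == 0L & truth == 1L))
}

#' Repeated k-fold cross-validation of the fever forest
#'
#' Diagnostic estimate of out-of-sample performance on the training set:
#' for each repeat the rows are partitioned into `cv_folds` folds; each fold
#' is held out once, a forest is fitted on the remainder and evaluated on the
#' fold at `prob_threshold`. A fold without positive rows has undefined
#' sensitivity, recorded as `NA` and excluded from the mean.
#'
#' @param train labeled `feature_table`.
#' @param cv_folds,cv_repeats folds per repeat and number of repeats.
#' @param n_trees trees per forest.
#' @param prob_threshold classification threshold on the fever probability.
#' @param seed integer seed.
#' @return list with `folds` (one row per repeat x fold: accuracy, precision,
#'   sensitivity) and `means` (NA-excluded column means).
#' @export
fever_rf_cv <- function(train, cv_folds = 10, cv_repeats = 3, n_trees = 100,
                        prob_threshold = 0.5, seed = 1L) {
  stopifnot(cv_folds >= 2, cv_repeats >= 1)
  set.seed(as.integer(seed))
  n <- nrow(train)
  rows <- vector("list", cv_folds * cv_repeats)
  k <- 0L
  for (r in seq_len(cv_repeats)) {
    fold_of <- sample(rep(seq_len(cv_folds), length.out = n))
    for (f in seq_len(cv_folds)) {
      hold <- fold_of == f
      k <- k + 1L
      if (length(unique(train$label[!hold])) < 2L) {
        # degenerate fold assignment: nothing to fit on; record and move on
        message("cv repeat ", r, " fold ", f,
                ": training part single-class, metrics recorded as NA")
        rows[[k]] <- data.frame(repeat_ = r, fold = f, accuracy = NA_real_,
                                precision = NA_real_, sensitivity = NA_real_)
        next
      }
      forest <- rf_fit(ft_subset(train, which(!hold)), n_trees,
                       seed = derive_seed(seed, 1000 * r + f))
      prob <- rf_prob(forest, ft_subset(train, which(hold)))
      pred <- as.integer(prob > prob_threshold)
      cnt <- eval_counts(pred, train$label[hold])
      met <- suppressWarnings(do.call(confusion_metrics, cnt))
      rows[[k]] <- data.frame(repeat_ = r, fold = f,
                              accuracy = met$accuracy,
                              precision = met$precision,
                              sensitivity = met$sensitivity)
    }
  }
  folds <- do.call(rbind, rows)
  list(folds = folds,
       means = colMeans(folds[, c("accuracy", "precision", "sensitivity")],
                        na.rm = TRUE))
}

#' Evaluate a fitted fever forest on a test set
#'
#' Predicts the fever probability for every test row, classifies as fever
#' when the probability exceeds `prob_threshold`, and reports confusion
#' counts with accuracy, precision and sensitivity.
#'
#' @param object a fitted `fever_rf` model (or a bare `ranger` forest).
#' @param test labeled `feature_table`.
#' @param prob_threshold classification threshold (default: the model's).
#' @return object of class `eval_report`.
#' @export
evaluate_fever <- function(object, test, prob_threshold = NULL) {
  if (nrow(test) == 0L) stop("test set is empty", call. = FALSE)
  if (inherits(object, "fever_rf")) {
    forest <- object$forest
    prob_threshold <- prob_threshold %||% object$prob_threshold
  } else {
    forest <- object
    prob_threshold <- prob_threshold %||% 0.5
  }
  prob <- rf_prob(forest, test)
  pred <- as.integer(prob > prob_threshold)
  cnt <- eval_counts(pred, test$label)
  met <- do.call(confusion_metrics, cnt)
  structure(c(met, list(n = nrow(test), prob_threshold = prob_threshold)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Fever classification report (threshold ", x$prob_threshold, ")\n",
      sep = "")
  cat(sprintf("  n = %d   TP %d  TN %d  FP %d  FN %d\n",
              x$n, x$tp, x$tn, x$fp, x$fn))
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("  accuracy %s   precision %s   sensitivity %s\n",
              pct(x$accuracy), pct(x$precision), pct(x$sensitivity)))
  invisible(x)
}

#' Fit the random-forest fever classifier
#'
#' The package's central fitting function. Following the evaluation
#' protocol, the labeled feature table is divided uniformly at random into a
#' training (80%) and an independent test (20%) set; a repeated 10-fold
#' cross-validation on the training set estimates out-of-sample performance
#' as an overfitting diagnostic; the final forest of `n_trees` trees is
#' fitted on the full training set and evaluated on the held-out test set at
#' a fever-probability threshold of 0.5. Variable importance is the mean
#' decrease in the Gini impurity.
#'
#' @param features labeled `feature_table` from
#'   [attach_labels_and_metadata()].
#' @param n_trees number of trees (default 100).
#' @param test_fraction held-out fraction (default 0.2).
#' @param cv_folds,cv_repeats cross-validation protocol; `cross_validate =
#'   FALSE` skips the diagnostic entirely.
#' @param prob_threshold fever-probability classification threshold.
#' @param split_unit `"record"` (default) or `"calf"`; see
#'   [split_features()].
#' @param cross_validate logical.
#' @param seed integer seed governing split, cross-validation and forest.
#' @return an object of class `fever_rf` with components `forest` (the
#'   underlying probability forest), `report` (held-out [evaluate_fever()]
#'   report), `cv` (cross-validation summary or `NULL`), `importance`
#'   (named, decreasing Gini importances), `train`/`test` tables and the
#'   protocol settings.
#' @seealso [predict.fever_rf()], [summary.fever_rf()], [plot.fever_rf()]
#' @export
fever_rf <- function(features, n_trees = 100, test_fraction = 0.2,
                     cv_folds = 10, cv_repeats = 3, prob_threshold = 0.5,
                     split_unit = c("record", "calf"),
                     cross_validate = TRUE, seed = 1L) {
  split_unit <- match.arg(split_unit)
  stopifnot("label" %in% names(features), prob_threshold > 0,
            prob_threshold < 1)
  parts <- split_features(features, test_fraction, split_unit,
                          seed = derive_seed(seed, 11))
  cv <- NULL
  if (cross_validate && cv_repeats >= 1) {
    cv <- fever_rf_cv(parts$train, cv_folds, cv_repeats, n_trees,
                      prob_threshold, seed = derive_seed(seed, 23))
  }
  forest <- rf_fit(parts$train, n_trees, seed = derive_seed(seed, 37))
  report <- evaluate_fever(forest, parts$test, prob_threshold)
  imp <- sort(ranger::importance(forest), decreasing = TRUE)
  structure(list(forest = forest, report = report, cv = cv,
                 importance = imp, train = parts$train, test = parts$test,
                 n_trees = n_trees, test_fraction = test_fraction,
                 cv_folds = cv_folds, cv_repeats = cv_repeats,
                 prob_threshold = prob_threshold, split_unit = split_unit,
                 seed = as.integer(seed)),
            class = "fever_rf")
}

#' Predict fever probabilities or classes
#'
#' @param object a `fever_rf` model.
#' @param newdata a `feature_table` (unlabeled rows allowed).
#' @param type `"prob"` for the fever probability, `"class"` for the 0/1
#'   decision at `threshold`.
#' @param threshold probability threshold for `type = "class"`.
#' @param ... unused.
#' @return numeric vector of probabilities, or integer 0/1 vector.
#' @export
predict.fever_rf <- function(object, newdata, type = c("prob", "class"),
                             threshold = object$prob_threshold, ...) {
  type <- match.arg(type)
  prob <- rf_prob(object$forest, newdata)
  if (type == "prob") prob else as.integer(prob > threshold)
}

#' @export
print.fever_rf <- function(x, ...) {
  cat(sprintf("Random-forest fever classifier (%d trees, %s-level %d/%d split, seed %d)\n",
              x$n_trees, x$split_unit,
              round(100 * (1 - x$test_fraction)),
              round(100 * x$test_fraction), x$seed))
  cat(sprintf("  training rows: %d (prevalence %.2f%%), test rows: %d\n",
              nrow(x$train), 100 * mean(x$train$label), nrow(x$test)))
  print(x$report)
  invisible(x)
}

#' Summarize a fitted fever classifier
#'
#' @param object a `fever_rf` model.
#' @param n_top number of top importances to display.
#' @param ... unused.
#' @return `object`, invisibly.
#' @export
summary.fever_rf <- function(object, n_top = 10, ...) {
  print(object)
  if (!is.null(object$cv)) {
    m <- object$cv$means
    cat(sprintf("  CV (%d x %d-fold) means: accuracy %.3f, precision %.3f, sensitivity %.3f\n",
                object$cv_repeats, object$cv_folds,
                m["accuracy"], m["precision"], m["sensitivity"]))
  }
  cat("  top variable importances (mean decrease in Gini):\n")
  top <- utils::head(object$importance, n_top)
  for (i in seq_along(top)) {
    cat(sprintf("    %2d. %-24s %.2f\n", i, names(top)[i], top[i]))
  }
  invisible(object)
}

#' Plot variable importances of the fever classifier
#'
#' Dot chart of the mean decrease in Gini impurity, largest on top.
#'
#' @param x a `fever_rf` model.
#' @param n_top number of features shown.
#' @param ... passed to [graphics::dotchart()].
#' @return `x`, invisibly.
#' @export
plot.fever_rf <- function(x, n_top = 20, ...) {
  imp <- rev(utils::head(x$importance, n_top))
  graphics::dotchart(unname(imp), labels = names(imp),
                     xlab = "Mean decrease in Gini index", ...)
  invisible(x)
}
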