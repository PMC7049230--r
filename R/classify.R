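#' Reproducible train/test split of a cohort
#'
#' Random partition into a training and a test set, optionally stratified
#' by class so the test set preserves case/control balance within one
#' sample per side.
#'
#' @param cohort Cohort tibble with `sample_id` and `group`.
#' @param n_train,n_test Partition sizes; must sum to the cohort size.
#' @param stratify Stratify by `group` (default `TRUE`).
#' @param seed Integer seed.
#' @return List with `train_ids` and `test_ids` (disjoint, exhaustive).
#' @export
split_train_test <- function(cohort, n_train, n_test, stratify = TRUE, seed = 1L) {
  n <- nrow(cohort)
  if (n_train + n_test != n) {
    abort(sprintf("n_train + n_test = %d but cohort has %d samples",
                  n_train + n_test, n))
  }
  if (n_train < 1 || n_test < 1) abort("both partitions must be nonempty")
  set.seed(as.integer(seed))
  if (!stratify) {
    train <- sample(cohort$sample_id, n_train)
  } else {
    # largest-remainder apportionment of the training quota across classes
    tab <- table(cohort$group)
    quota <- n_train * as.numeric(tab) / n
    base <- floor(quota)
    rem <- n_train - sum(base)
    if (rem > 0) {
      extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    train <- unlist(purrr::map2(names(tab), base, function(g, k) {
      sample(cohort$sample_id[cohort$group == g], k)
    }), use.names = FALSE)
  }
  list(train_ids = sort(train),
       test_ids = sort(setdiff(cohort$sample_id, train)))
}

#' Confusion-matrix metrics for a two-class screen
#'
#' Counts and rates for predicted vs observed labels: sensitivity
#' `tp / (tp + fn)`, specificity `tn / (tn + fp)`, accuracy
#' `(tp + tn) / n`, reported as exact percentages plus the rounded
#' integers conventional in diagnostic reporting.
#'
#' @param predicted,observed Equal-length label vectors.
#' @param positive Positive-class label (default `"POAG"`).
#' @param negative Negative-class label (default `"CTRL"`).
#' @return Object of class `confusion_metrics` (a list; see
#'   [glance.confusion_metrics()]): `tp`, `fn`, `tn`, `fp`,
#'   `sensitivity`, `specificity`, `accuracy` (exact percent) and
#'   `*_rounded` integer percents.
#' @export
#' @examples
#' p <- rep(c("POAG", "CTRL"), c(34, 41))
#' o <- rep(c("POAG", "CTRL"), c(38, 37))
#' confusion_metrics(p, o)
confusion_metrics <- function(predicted, observed,
                              positive = "POAG", negative = "CTRL") {
  if (length(predicted) != length(observed)) {
    abort("predicted and observed must have equal length")
  }
  allowed <- c(positive, negative)
  bad <- setdiff(unique(c(as.character(predicted), as.character(observed))), allowed)
  if (length(bad) > 0) {
    abort(paste0("labels outside {", positive, ", ", negative, "}: ",
                 paste(bad, collapse = ", ")))
  }
  tp <- sum(predicted == positive & observed == positive)
  fn <- sum(predicted == negative & observed == positive)
  tn <- sum(predicted == negative & observed == negative)
  fp <- sum(predicted == positive & observed == negative)
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  acc <- 100 * (tp + tn) / length(observed)
  structure(
    list(
      tp = tp, fn = fn, tn = tn, fp = fp,
      positive = positive, negative = negative,
      sensitivity = sens, specificity = spec, accuracy = acc,
      sensitivity_rounded = round(sens), specificity_rounded = round(spec),
      accuracy_rounded = round(acc)
    ),
    class = "confusion_metrics"
  )
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(
    "Confusion metrics (%s positive): %d/%d %s, %d/%d %s correct\n",
    x$positive, x$tp, x$tp + x$fn, x$positive, x$tn, x$tn + x$fp, x$negative
  ))
  cat(sprintf("  sensitivity %g%%, specificity %g%%, accuracy %g%%\n",
              x$sensitivity_rounded, x$specificity_rounded, x$accuracy_rounded))
  invisible(x)
}

#' Random-forest case/control classifier on autoantibody profiles
#'
#' Fits a bagged-tree ensemble (majority vote) on the training samples of
#' an imputed NFI feature table and predicts the held-out test samples —
#' the single-split protocol used to gauge the diagnostic potential of an
#' autoantibody panel. No cross-validation or calibration is attempted;
#' for small panels this is an optimistic point estimate and is documented
#' as such.
#'
#' @param nfi Wide NFI tibble with no missing values (run
#'   [preprocess_array()] first).
#' @param cohort Cohort tibble with `sample_id` and `group`.
#' @param split List from [split_train_test()].
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split; default floor(sqrt(p)).
#' @param seed Integer seed; the fit is deterministic given it.
#' @return Object of class `aab_forest`: the fitted model, a
#'   `predictions` tibble (`sample_id`, `observed`, `predicted`) and
#'   `metrics` ([confusion_metrics()]).
#' @export
fit_autoantibody_forest <- function(nfi, cohort, split, n_trees = 500,
                                    mtry = NULL, seed = 1L) {
  targets <- setdiff(names(nfi), "sample_id")
  joined <- dplyr::left_join(nfi, dplyr::select(cohort, "sample_id", "group"),
                             by = "sample_id")
  if (anyNA(joined[targets])) abort("feature table contains missing values; impute first")
  train <- joined[joined$sample_id %in% split$train_ids, , drop = FALSE]
  test <- joined[joined$sample_id %in% split$test_ids, , drop = FALSE]
  if (length(unique(train$group)) < 2) {
    abort("training set contains a single class; cannot fit a classifier")
  }
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(length(targets))))
  set.seed(as.integer(seed))
  model <- randomForest::randomForest(
    x = as.data.frame(train[targets]),
    y = factor(train$group),
    ntree = n_trees, mtry = mtry
  )
  pred <- stats::predict(model, newdata = as.data.frame(test[targets]))
  predictions <- tibble::tibble(
    sample_id = test$sample_id,
    observed = test$group,
    predicted = as.character(pred)
  )
  metrics <- confusion_metrics(predictions$predicted, predictions$observed)
  structure(
    list(model = model, predictions = predictions, metrics = metrics,
         n_trees = n_trees, mtry = mtry, seed = seed),
    class = "aab_forest"
  )
}

#' @export
print.aab_forest <- function(x, ...) {
  cat(sprintf("Random-forest autoantibody classifier (%d trees, mtry %d)\n",
              x$n_trees, x$mtry))
  print(x$metrics)
  invisible(x)
}
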