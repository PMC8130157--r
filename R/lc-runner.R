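# Attach run metadata and the lc_raw class to a score record table.
new_lc_raw <- function(df, dataset_id, estimator_id, metric) {
  df$dataset_id <- dataset_id
  df$estimator_id <- estimator_id
  df$metric <- metric
  df <- df[, c("dataset_id", "estimator_id", "metric",
               "split", "subset", "train_size", "score")]
  rownames(df) <- NULL
  class(df) <- c("lc_raw", "data.frame")
  df
}

#' @export
print.lc_raw <- function(x, ...) {
  cat(sprintf("raw learning-curve scores: %d records (%d splits x up to %d subsets), metric %s\n",
              nrow(x), length(unique(x$split)), length(unique(x$subset)),
              x$metric[1]))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("... %d more rows\n", nrow(x) - 5))
  invisible(x)
}

#' Score predictions against observed responses
#'
#' The learning-curve metric. Only mean absolute error is registered:
#' `MAE = mean(|predicted - actual|)`.
#'
#' @param predicted,actual Equal-length non-empty numeric vectors.
#' @param metric Metric name; only `"mae"`.
#' @return The scalar score.
#' @export
score_predictions <- function(predicted, actual, metric = "mae") {
  metric <- match.arg(metric, c("mae"))
  if (length(predicted) != length(actual))
    stop(sprintf("length mismatch: %d predictions vs %d actuals",
                 length(predicted), length(actual)))
  if (length(predicted) == 0) stop("empty prediction vector")
  bad <- sum(!is.finite(predicted))
  if (bad > 0) stop(sprintf("%d non-finite prediction(s)", bad))
  mean(abs(predicted - actual))
}

#' Built-in reference estimators
#'
#' Returns a pluggable estimator satisfying the fit/predict contract used
#' by [run_learning_curve()]: `fit(x, y, x_val, y_val, patience)` returns
#' an opaque model, `predict(model, x)` returns one prediction per row.
#' Available:
#' \describe{
#'   \item{`"mean"`}{predicts the training-set mean everywhere (the
#'     floor any learning model must beat).}
#'   \item{`"knn"`}{k-nearest-neighbor regression (via [caret::knnreg()]),
#'     `k = 5` by default. Ignores the validation set (no iterative
#'     training to stop early).}
#'   \item{`"gbdt"`}{gradient-boosted tree regression (via
#'     \pkg{xgboost}) with early stopping on the validation set: training
#'     halts when validation error fails to improve for `patience`
#'     boosting rounds (default 50), under a cap of 500 rounds.}
#' }
#'
#' @param name Estimator name.
#' @param k Neighbor count for `"knn"`.
#' @param max_rounds Boosting-round cap for `"gbdt"`.
#' @return List with elements `id`, `fit`, `predict`.
#' @export
builtin_estimators <- function(name, k = 5, max_rounds = 500) {
  known <- c("mean", "knn", "gbdt")
  if (!is.character(name) || length(name) != 1 || !name %in% known)
    stop("unknown estimator '", paste(name, collapse = ","),
         "'; available: ", paste(known, collapse = ", "))
  switch(name,
    mean = list(
      id = "mean",
      fit = function(x, y, x_val, y_val, patience) mean(y),
      predict = function(model, x) rep(model, nrow(x))),
    knn = list(
      id = "knn",
      fit = function(x, y, x_val, y_val, patience)
        caret::knnreg(x, y, k = min(k, length(y))),
      predict = function(model, x) as.numeric(stats::predict(model, x))),
    gbdt = list(
      id = "gbdt",
      fit = function(x, y, x_val, y_val, patience) {
        dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
        dval <- xgboost::xgb.DMatrix(x_val, label = y_val, nthread = 1)
        rounds <- if (is.finite(patience)) max_rounds else max_rounds
        xgboost::xgb.train(
          params = list(objective = "reg:squarederror", eta = 0.1,
                        max_depth = 6, nthread = 1),
          data = dtrain, nrounds = rounds,
          evals = list(val = dval),
          early_stopping_rounds = if (is.finite(patience)) patience else NULL,
          verbose = 0)
      },
      predict = function(model, x)
        as.numeric(stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1)))))
}

#' Generate raw learning-curve scores for a dataset
#'
#' Trains one model per (split, subset) pair -- N x K models in total --
#' and scores each on its split's held-out test set. Within a split, all K
#' models share the same validation and test sets; training subsets are
#' nested prefixes of the shuffled training list. A failed training leaves
#' a gap (`NA` score) and the run continues; downstream quantiles use the
#' splits available at each size. Records are mutually independent, so
#' sequential execution (used here) and any parallel dispatch must agree.
#'
#' @param dataset A [gen_response_dataset()]-style data frame (feature
#'   columns `ge_*`/`dd_*`, label column `response`).
#' @param plan A [make_splits()] plan for `nrow(dataset)` samples.
#' @param schedule A [make_schedule()] schedule for the plan's training size.
#' @param estimator An estimator contract, e.g. from [builtin_estimators()].
#' @param metric Metric name (only `"mae"`).
#' @param patience Early-stopping patience passed to the estimator
#'   (boosting rounds for trees, epochs for epoch-based learners);
#'   `Inf` disables early stopping.
#' @param dataset_id Identifier recorded with the scores.
#' @param verbose Emit a progress message per (split, subset).
#' @return An `"lc_raw"` score table with `plan$n_splits *
#'   schedule$realized_k` records.
#' @export
run_learning_curve <- function(dataset, plan, schedule, estimator,
                               metric = "mae", patience = 50,
                               dataset_id = "dataset", verbose = FALSE) {
  stopifnot(inherits(plan, "split_plan"), inherits(schedule, "subset_schedule"))
  if (plan$n_samples != nrow(dataset))
    stop("plan was built for a different number of samples than the dataset")
  x <- response_features(dataset)
  y <- response_values(dataset)
  K <- schedule$realized_k
  recs <- vector("list", plan$n_splits * K)
  n_failed <- 0L
  for (n in seq_len(plan$n_splits)) {
    sp <- plan$splits[[n]]
    x_val <- x[sp$val, , drop = FALSE]; y_val <- y[sp$val]
    x_test <- x[sp$test, , drop = FALSE]; y_test <- y[sp$test]
    for (k in seq_len(K)) {
      idx <- nested_subset(plan, n, schedule, k)
      score <- tryCatch({
        model <- estimator$fit(x[idx, , drop = FALSE], y[idx],
                               x_val, y_val, patience)
        score_predictions(estimator$predict(model, x_test), y_test, metric)
      }, error = function(e) {
        warning(sprintf("training failed for split %d, subset %d (m = %d): %s",
                        n, k, schedule$sizes[k], conditionMessage(e)))
        NA_real_
      })
      if (is.na(score)) n_failed <- n_failed + 1L
      if (verbose)
        message(sprintf("split %d/%d subset %d/%d (m = %d): score = %s",
                        n, plan$n_splits, k, K, schedule$sizes[k], format(score)))
      recs[[(n - 1) * K + k]] <- data.frame(
        split = n, subset = k, train_size = schedule$sizes[k], score = score)
    }
  }
  if (n_failed == plan$n_splits * K) stop("all trainings failed")
  new_lc_raw(do.call(rbind, recs), dataset_id = dataset_id,
             estimator_id = estimator$id, metric = metric)
}

#' Read / write raw learning-curve score tables
#'
#' The interchange format between the runner and the curve-fitting stage:
#' tab-delimited text with header `dataset_id estimator_id metric split
#' subset train_size score`, scores serialized at full precision.
#'
#' @param x An `"lc_raw"` table.
#' @param path File path.
#' @return `read_lc_scores()` returns the `"lc_raw"` table; the writer
#'   returns `path` invisibly.
#' @export
write_lc_scores <- function(x, path) {
  write_delim_precise(as.data.frame(x), path)
}

#' @rdname write_lc_scores
#' @export
read_lc_scores <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("dataset_id", "estimator_id", "metric", "split", "subset",
            "train_size", "score")
  if (!all(need %in% names(df)))
    stop("not a learning-curve score file: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  class(df) <- c("lc_raw", "data.frame")
  df
}
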