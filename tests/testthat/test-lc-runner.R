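test_that("score_predictions computes MAE and rejects malformed input", {
  expect_equal(score_predictions(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(score_predictions(c(0, 1), c(1, 0)), 1)
  set.seed(15)
  p <- runif(100); a <- runif(100)
  expect_equal(score_predictions(p, a), oracle_mae(p, a), tolerance = 1e-15)
  expect_error(score_predictions(1:3, 1:4), "mismatch")
  expect_error(score_predictions(numeric(0), numeric(0)), "empty")
  expect_error(score_predictions(c(1, NaN, Inf), c(1, 2, 3)), "2 non-finite")
})

test_that("builtin estimators honor the fit/predict contract", {
  expect_error(builtin_estimators("zzz"), "available: mean, knn, gbdt")
  cm <- builtin_estimators("mean")
  model <- cm$fit(matrix(0, 4, 2), c(0, 0, 1, 1), NULL, NULL, Inf)
  expect_equal(cm$predict(model, matrix(0, 2, 2)), c(0.5, 0.5))
  expect_equal(score_predictions(cm$predict(model, matrix(0, 2, 2)), c(0, 1)), 0.5)

  # 1-NN recovers a training point exactly in the noiseless limit
  nn <- builtin_estimators("knn", k = 1)
  x <- matrix(rnorm(40), 20, 2)
  y <- rowSums(x)
  m <- nn$fit(x, y, NULL, NULL, Inf)
  expect_equal(nn$predict(m, x[7, , drop = FALSE]), y[7])
})

test_that("gradient-boosting adapter stops before the round cap on a plateau", {
  ds <- gen_response_dataset(n_cells = 40, n_drugs = 40, seed = 2)
  plan <- make_splits(nrow(ds), n_splits = 1, base_seed = 2)
  est <- builtin_estimators("gbdt")
  x <- response_features(ds); y <- response_values(ds)
  sp <- plan$splits[[1]]
  m <- est$fit(x[sp$train, ], y[sp$train], x[sp$val, ], y[sp$val], patience = 50)
  expect_lt(xgboost::xgb.get.num.boosted.rounds(m), 500)
  pred <- est$predict(m, x[sp$test, ])
  expect_length(pred, length(sp$test))
  expect_true(all(is.finite(pred)))
})

test_that("run_learning_curve yields one test-set score per (split, subset)", {
  ds <- gen_response_dataset(n_cells = 30, n_drugs = 20, seed = 6)
  plan <- make_splits(nrow(ds), n_splits = 3, base_seed = 6)
  sched <- make_schedule(plan$train_size, K = 4, m_min = 30)
  est <- builtin_estimators("mean")
  raw <- run_learning_curve(ds, plan, sched, est, dataset_id = "toy")
  expect_s3_class(raw, "lc_raw")
  expect_equal(nrow(raw), 3 * 4)
  expect_equal(anyDuplicated(raw[, c("split", "subset")]), 0)

  # closed-form oracle: the constant-mean model scores the MAE between the
  # training-subset mean and that split's test responses
  y <- response_values(ds)
  for (i in seq_len(nrow(raw))) {
    idx <- nested_subset(plan, raw$split[i], sched, raw$subset[i])
    y_test <- y[plan$splits[[raw$split[i]]]$test]
    expect_equal(raw$score[i], oracle_mae(rep(mean(y[idx]), length(y_test)), y_test),
                 tolerance = 1e-12)
  }
})

test_that("runs are deterministic and rerunnable", {
  ds <- gen_response_dataset(n_cells = 25, n_drugs = 20, seed = 10)
  plan <- make_splits(nrow(ds), n_splits = 2, base_seed = 10)
  sched <- make_schedule(plan$train_size, K = 4, m_min = 25)
  est <- builtin_estimators("knn")
  r1 <- run_learning_curve(ds, plan, sched, est)
  r2 <- run_learning_curve(ds, plan, sched, est)
  expect_identical(r1, r2)
})

test_that("an estimator failure leaves a gap and the run continues", {
  ds <- gen_response_dataset(n_cells = 25, n_drugs = 20, seed = 12)
  plan <- make_splits(nrow(ds), n_splits = 2, base_seed = 12)
  sched <- make_schedule(plan$train_size, K = 4, m_min = 25)
  flaky <- list(id = "flaky",
                fit = function(x, y, xv, yv, patience) {
                  if (nrow(x) == 25) stop("boom")
                  mean(y)
                },
                predict = function(model, x) rep(model, nrow(x)))
  # one warning per failing split (two splits hit the m = 25 subset)
  expect_warning(expect_warning(
    raw <- run_learning_curve(ds, plan, sched, flaky), "boom"), "boom")
  expect_equal(sum(is.na(raw$score)), 2)      # one gap per split
  expect_equal(nrow(raw), 8)
  always_fail <- list(id = "dead",
                      fit = function(...) stop("no"),
                      predict = function(...) NULL)
  expect_error(suppressWarnings(run_learning_curve(ds, plan, sched, always_fail)),
               "all trainings failed")
})

test_that("median score decreases with training size for a learnable signal", {
  # Spearman correlation between m_k and the median score should be <= 0;
  # allow at most 2 violations over 20 generator seeds
  violations <- 0
  for (seed in 1:20) {
    ds <- gen_response_dataset(n_cells = 30, n_drugs = 30, noise_sd = 0.1,
                               seed = seed)
    plan <- make_splits(nrow(ds), n_splits = 3, base_seed = seed)
    sched <- make_schedule(plan$train_size, K = 4, m_min = 40)
    raw <- run_learning_curve(ds, plan, sched, builtin_estimators("knn"))
    med <- sapply(split(raw$score, raw$train_size), median)
    sizes <- sort(unique(raw$train_size))
    rho <- cor(sizes, med[as.character(sizes)], method = "spearman")
    if (rho > 0) violations <- violations + 1
  }
  expect_lte(violations, 2)
})

test_that("raw score tables round-trip through the delimited interchange format", {
  p <- powerlaw_params(0.7, -0.35, 0.02)
  raw <- gen_powerlaw_scores(p, c(100, 300, 900, 2700), n_splits = 50,
                             noise_sd0 = 0.004, seed = 5)
  expect_equal(nrow(raw), 200)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lc_scores(raw, path)
  expect_equal(length(readLines(path)), 201)   # header + 200 data rows
  back <- read_lc_scores(path)
  expect_equal(as.data.frame(back), as.data.frame(raw))
  expect_identical(back$score, raw$score)      # %.17g is bit-faithful
  expect_error(read_lc_scores(withr::local_tempfile(lines = "a\tb", fileext = ".tsv")),
               "missing column")
})
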