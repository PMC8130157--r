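test_that("powerlaw_eval matches closed forms and its asymptote", {
  expect_equal(powerlaw_eval(powerlaw_params(1, -0.5, 0.1), 100), 0.2)
  p <- powerlaw_params(2.3, -0.17, 0.06)
  expect_equal(powerlaw_eval(p, 1), p$a + p$c)
  # asymptote: the a*m^b term vanishes for large m
  steep <- powerlaw_params(2.3, -0.5, 0.06)
  expect_lt(abs(powerlaw_eval(steep, 1e12) - steep$c), 1e-3 * steep$a)
  expect_error(powerlaw_eval(p, 0))
  expect_error(powerlaw_eval(p, -5))
  expect_error(powerlaw_params(1, -1.5, 0))   # exponent outside (-1, 0)
  expect_error(powerlaw_params(-1, -0.5, 0))
  expect_error(powerlaw_params(1, -0.5, -0.01))
})

test_that("small-data truncation drops exactly the sizes below the cutoff", {
  p <- powerlaw_params(1, -0.4, 0.03)
  raw <- gen_powerlaw_scores(p, c(10, 100, 1000, 10000, 100000), n_splits = 2)
  expect_equal(truncate_small_data(raw, 0), raw)
  cut <- truncate_small_data(raw, 100)
  expect_equal(sort(unique(cut$train_size)), c(100, 1000, 10000, 100000))
  expect_error(truncate_small_data(raw, 1000), "at least 4")
})

test_that("default weights are sizes normalized by the largest size", {
  fit <- fit_powerlaw_weighted(c(100, 200, 400, 800),
                               powerlaw_eval(powerlaw_params(1, -0.5, 0.01),
                                             c(100, 200, 400, 800)))
  expect_equal(fit$weights, c(0.125, 0.25, 0.5, 1.0))
  expect_equal(fit_powerlaw_weighted(c(100, 200, 400, 50),
                                     c(0.2, 0.15, 0.12, 0.3))$weights,
               c(50, 100, 200, 400) / 400)   # sorted by size, alpha_K = 1
})

test_that("noiseless points are recovered to high precision", {
  sizes <- round(10^seq(2, 5, length.out = 8))
  gp <- powerlaw_params(0.8, -0.3, 0.04)
  fit <- fit_powerlaw_weighted(sizes, powerlaw_eval(gp, sizes))
  expect_equal(fit$params$a, gp$a, tolerance = 1e-4)
  expect_equal(fit$params$b, gp$b, tolerance = 1e-4)
  expect_equal(fit$params$c, gp$c, tolerance = 1e-4)
  expect_lt(fit$mae_fit, 1e-10)
  expect_gt(fit$r2_fit, 1 - 1e-10)
  expect_true(fit$converged)
})

test_that("the fitted solution beats a bounded 20^3 grid oracle", {
  sizes <- round(10^seq(2, 4.5, length.out = 8))
  for (seed in 1:20) {
    set.seed(seed)
    gp <- powerlaw_params(runif(1, 0.3, 3), runif(1, -0.7, -0.1),
                          runif(1, 0.01, 0.1))
    raw <- gen_powerlaw_scores(gp, sizes, n_splits = 1, noise_sd0 = 0.002,
                               seed = 1000 + seed)
    fit <- fit_powerlaw_weighted(raw$train_size, raw$score)
    w <- sort(sizes) / max(sizes)
    obj_fit <- oracle_objective(unlist(fit$params), sort(sizes),
                                raw$score[order(raw$train_size)], w)
    obj_grid <- oracle_grid_best(sort(sizes),
                                 raw$score[order(raw$train_size)], w, n = 20)
    expect_lte(obj_fit, obj_grid + 1e-12)
  }
})

test_that("scaling all scores by lambda scales a and c and leaves b fixed", {
  sizes <- round(10^seq(2, 5, length.out = 9))
  s <- powerlaw_eval(powerlaw_params(1.1, -0.45, 0.05), sizes)
  set.seed(3); s <- s + rnorm(9, sd = 1e-4)
  f1 <- fit_powerlaw_weighted(sizes, s)
  for (lambda in c(0.5, 3)) {
    f2 <- fit_powerlaw_weighted(sizes, lambda * s)
    expect_equal(f2$params$a, lambda * f1$params$a, tolerance = 1e-4)
    expect_equal(f2$params$c, lambda * f1$params$c, tolerance = 1e-4)
    expect_equal(f2$params$b, f1$params$b, tolerance = 1e-4)
  }
})

test_that("goodness_of_fit matches a residual-loop oracle and handles degenerate input", {
  p <- powerlaw_params(1, -0.5, 0.02)
  sizes <- c(100, 400, 1600, 6400)
  on_curve <- powerlaw_eval(p, sizes)
  g <- goodness_of_fit(sizes, on_curve, p)
  expect_equal(g$mae_fit, 0)
  expect_equal(g$r2_fit, 1)
  g2 <- goodness_of_fit(sizes, on_curve + 0.01, p)
  expect_equal(g2$mae_fit, 0.01)
  set.seed(9)
  obs <- on_curve + rnorm(4, sd = 0.005)
  g3 <- goodness_of_fit(sizes, obs, p)
  expect_equal(g3$mae_fit, oracle_mae(powerlaw_eval(p, sizes), obs),
               tolerance = 1e-12)
  expect_equal(g3$r2_fit,
               1 - sum((obs - on_curve)^2) / sum((obs - mean(obs))^2),
               tolerance = 1e-12)
  g4 <- goodness_of_fit(sizes, rep(0.5, 4), p)
  expect_false(g4$r2_defined)
})

test_that("per-split fitting returns one fit per split and handles noise-free ties", {
  sizes <- round(10^seq(2, 5, length.out = 10))
  gp <- powerlaw_params(0.9, -0.4, 0.03)
  raw0 <- gen_powerlaw_scores(gp, sizes, n_splits = 5)
  fits <- fit_per_split(raw0)
  expect_length(fits, 5)
  triples <- t(sapply(fits, function(f) unlist(f$params)))
  expect_equal(max(apply(triples, 2, function(v) diff(range(v)))), 0,
               tolerance = 1e-8)                     # identical splits
  single <- fit_per_split(raw0[raw0$split == 1, ])
  expect_length(single, 1)

  raw <- gen_powerlaw_scores(gp, sizes, n_splits = 20, noise_sd0 = 1e-4,
                             seed = 2)
  b_hat <- sapply(fit_per_split(raw), function(f) f$params$b)
  expect_lt(abs(median(b_hat) - gp$b), 0.02 * abs(gp$b))
})

test_that("quantile curves bracket the central curve and match a sort-interpolate oracle", {
  sizes <- round(10^seq(2, 5, length.out = 10))
  gp <- powerlaw_params(1.2, -0.5, 0.04)
  raw <- gen_powerlaw_scores(gp, sizes, n_splits = 15, noise_sd0 = 0.002,
                             seed = 14)
  fits <- fit_per_split(raw)
  qc <- build_quantile_curves(fits, sizes)
  expect_true(all(qc$quantiles$q0.1 <= qc$quantiles$q0.5 + 1e-15))
  expect_true(all(qc$quantiles$q0.5 <= qc$quantiles$q0.9 + 1e-15))
  for (j in seq_along(sizes)) {
    for (p in c(0.1, 0.5, 0.9)) {
      expect_equal(qc$quantiles[j, paste0("q", p)],
                   unname(oracle_quantile(qc$values[, j], p)),
                   tolerance = 1e-12)
    }
  }
  # single split: all three series coincide with the one curve
  qc1 <- build_quantile_curves(fits[1], sizes)
  expect_equal(qc1$quantiles$q0.1, qc1$quantiles$q0.9)
  expect_equal(qc1$quantiles$q0.5, powerlaw_eval(fits[[1]]$params, sizes))
})

test_that("the fitted central curve is strictly decreasing and convex in m", {
  sizes <- round(10^seq(2, 5, length.out = 10))
  raw <- gen_powerlaw_scores(powerlaw_params(0.9, -0.35, 0.05), sizes,
                             n_splits = 10, noise_sd0 = 0.001, seed = 4)
  qc <- build_quantile_curves(fit_per_split(raw), sizes)
  grid_m <- 10^seq(2, 5, length.out = 200)
  y <- powerlaw_eval(qc$fits$central$params, grid_m)
  expect_true(all(diff(y) < 0))
  expect_true(all(diff(diff(y) / diff(grid_m)) > 0))
})

test_that("power-law fits survive the JSON round trip bit-faithfully", {
  sizes <- round(10^seq(2, 4.8, length.out = 7))
  fit <- fit_powerlaw_weighted(sizes,
                               powerlaw_eval(powerlaw_params(1, -0.5, 0.03),
                                             sizes) + 1e-4)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, path)
  back <- read_fit(path)
  expect_identical(back$params$a, fit$params$a)
  expect_identical(back$params$b, fit$params$b)
  expect_identical(back$params$c, fit$params$c)
  expect_identical(back$m_K, fit$m_K)
  expect_equal(back$weights, fit$weights)
})
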