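#' Power-law learning-curve parameters
#'
#' Constructs and validates the parameter triple of the learning-curve model
#' \deqn{s(m) = a m^{b} + c,}
#' where `a > 0` scales the curve, `b` (the scaling exponent, in `(-1, 0)`)
#' sets the steepness of the power-law region, and `c >= 0` is the
#' irreducible asymptotic error the curve plateaus to as the training size
#' `m` grows.
#'
#' @param a Positive scale parameter.
#' @param b Scaling exponent, strictly inside `(-1, 0)`.
#' @param c Non-negative irreducible error.
#'
#' @return An object of class `"powerlaw_params"`: a named list with
#'   elements `a`, `b`, `c`.
#' @examples
#' p <- powerlaw_params(a = 1, b = -0.5, c = 0.05)
#' powerlaw_eval(p, c(100, 400))
#' @export
powerlaw_params <- function(a, b, c) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            length(a) == 1, length(b) == 1, length(c) == 1)
  if (!is.finite(a) || a <= 0) stop("'a' must be a positive finite number")
  if (!is.finite(b) || b <= -1 || b >= 0)
    stop("'b' must lie strictly inside (-1, 0)")
  if (!is.finite(c) || c < 0) stop("'c' must be non-negative")
  structure(list(a = a, b = b, c = c), class = "powerlaw_params")
}

#' @export
print.powerlaw_params <- function(x, ...) {
  cat(sprintf("power law s(m) = a*m^b + c  with a = %.6g, b = %.6g, c = %.6g\n",
              x$a, x$b, x$c))
  invisible(x)
}

#' Evaluate the power law at given training sizes
#'
#' @param params A [powerlaw_params()] object (or a list with `a`, `b`, `c`).
#' @param m Vector of positive training sizes (need not be integer).
#'
#' @return Numeric vector `a * m^b + c`.
#' @export
powerlaw_eval <- function(params, m) {
  stopifnot(is.numeric(m))
  if (any(!is.finite(m)) || any(m <= 0)) stop("training sizes 'm' must be positive")
  params$a * m^params$b + params$c
}

#' Drop learning-curve scores from the small-data region
#'
#' Removes all raw learning-curve records with training size below `m_kmin`.
#' Scores at very small training sizes sit in the near-random-guessing
#' regime that the power law does not model, so they are excluded before
#' fitting; the cutoff is a user decision (typically made by inspecting the
#' log-log plot).
#'
#' @param raw A raw learning-curve score table as returned by
#'   [run_learning_curve()] or [gen_powerlaw_scores()].
#' @param m_kmin Non-negative size cutoff; records with `train_size < m_kmin`
#'   are dropped. `0` keeps everything.
#'
#' @return The filtered table. Errors if fewer than 4 distinct training
#'   sizes remain (a 3-parameter fit would be underdetermined).
#' @export
truncate_small_data <- function(raw, m_kmin) {
  stopifnot(is.data.frame(raw), is.numeric(m_kmin), length(m_kmin) == 1, m_kmin >= 0)
  out <- raw[raw$train_size >= m_kmin, , drop = FALSE]
  n_sizes <- length(unique(out$train_size))
  if (n_sizes < 4)
    stop(sprintf(paste0("only %d distinct training sizes remain after truncation ",
                        "at m_kmin = %s; at least 4 are required to fit 3 parameters"),
                 n_sizes, format(m_kmin)))
  rownames(out) <- NULL
  out
}

# Weighted sum-of-squares objective for a parameter triple; the unit the
# grid-search fallback and the optimizer both minimize.
powerlaw_objective <- function(theta, m, s, w) {
  r <- s - (theta[1] * m^theta[2] + theta[3])
  sum(w * r^2)
}

# Coarse bounded grid search over (a, b, c); used only as the fallback when
# the Levenberg-Marquardt multi-start fails to converge.
powerlaw_grid_search <- function(m, s, w, n = 25) {
  c_hi <- min(s)
  c_grid <- seq(0, c_hi * 0.999, length.out = n)
  b_grid <- seq(-0.999, -0.001, length.out = n)
  s_max <- max(s)
  a_grid <- exp(seq(log(1e-4 * s_max), log(1e3 * s_max), length.out = n))
  best <- NULL
  best_obj <- Inf
  for (a in a_grid) for (b in b_grid) {
    pred0 <- a * m^b
    for (cc in c_grid) {
      obj <- sum(w * (s - pred0 - cc)^2)
      if (obj < best_obj) {
        best_obj <- obj
        best <- c(a, b, cc)
      }
    }
  }
  list(theta = best, objective = best_obj)
}

#' Fit the power law to learning-curve scores by weighted least squares
#'
#' Minimizes the size-weighted residual sum of squares
#' \deqn{\sum_k \alpha_k (s_k - a m_k^b - c)^2}
#' subject to `a > 0`, `-1 < b < 0` and `0 <= c < min(s)`. The default
#' weights are \eqn{\alpha_k = m_k / m_K} (normalized by the largest size),
#' which prioritizes larger training subsets and damps the influence of
#' scores close to the random-guessing regime.
#'
#' Optimization uses bounded Levenberg-Marquardt ([minpack.lm::nls.lm()])
#' with an analytic residual Jacobian. The starting point sets
#' `c0 = 0.9 * min(s)` and obtains `(a0, b0)` from an ordinary linear
#' regression of `log(s - c0)` on `log(m)`; four further starts jitter the
#' `c0` fraction. If no start converges, a coarse bounded grid search
#' supplies the returned solution and `converged` is set to `FALSE`.
#'
#' @param sizes Vector of positive training sizes (at least 4 distinct).
#' @param scores Vector of error scores, same length as `sizes`.
#' @param weights Optional positive weights; defaults to `sizes / max(sizes)`.
#'
#' @return An object of class `"powerlaw_fit"`: list with `params`
#'   ([powerlaw_params()]), `sizes`, `m_K` (largest size), `weights`,
#'   `objective`, `mae_fit`, `r2_fit`, `converged`.
#' @examples
#' m <- round(10^seq(2, 5, length.out = 8))
#' s <- 0.8 * m^-0.3 + 0.04
#' fit <- fit_powerlaw_weighted(m, s)
#' fit$params
#' @export
fit_powerlaw_weighted <- function(sizes, scores, weights = NULL) {
  stopifnot(is.numeric(sizes), is.numeric(scores), length(sizes) == length(scores))
  if (length(unique(sizes)) < 4)
    stop("at least 4 distinct sizes are required for a 3-parameter fit")
  if (any(sizes <= 0)) stop("sizes must be positive")
  if (any(!is.finite(scores))) stop("scores must be finite")
  ord <- order(sizes)
  m <- as.numeric(sizes[ord])
  s <- as.numeric(scores[ord])
  m_K <- max(m)
  w <- if (is.null(weights)) m / m_K else as.numeric(weights)[ord]
  if (any(w <= 0)) stop("weights must be positive")

  s_min <- min(s)
  c_upper <- max(s_min * (1 - 1e-9), 0)
  lower <- c(a = 1e-12, b = -1 + 1e-9, c = 0)
  upper <- c(a = Inf, b = -1e-9, c = c_upper)
  sw <- sqrt(w)

  resid_fn <- function(theta) sw * (s - (theta[1] * m^theta[2] + theta[3]))
  jac_fn <- function(theta) {
    mb <- m^theta[2]
    cbind(-sw * mb, -sw * theta[1] * mb * log(m), -sw)
  }

  start_for <- function(c_frac) {
    c0 <- min(c_frac * s_min, c_upper)
    pos <- s - c0
    pos[pos <= 0] <- min(pos[pos > 0], 1e-12)
    co <- stats::coef(stats::lm(log(pos) ~ log(m)))
    b0 <- min(max(co[2], lower["b"] + 1e-6), upper["b"] - 1e-6)
    a0 <- max(exp(co[1]), lower["a"])
    c(a = unname(a0), b = unname(b0), c = c0)
  }

  starts <- lapply(c(0.9, 0.5, 0.99, 0, 0.75), start_for)
  # a coarse-grid seed guards against LM stalling far from the optimum on
  # ill-conditioned instances
  coarse <- powerlaw_grid_search(m, s, w, n = 16)
  starts <- c(starts, list(pmin(pmax(coarse$theta, lower + 1e-10),
                                pmin(upper, 1e12))))
  best <- NULL
  best_obj <- Inf
  for (theta0 in starts) {
    res <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = theta0, fn = resid_fn, jac = jac_fn,
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 1000, ftol = 1e-14, ptol = 1e-14))),
      error = function(e) NULL)
    if (is.null(res)) next
    th <- res$par
    obj <- powerlaw_objective(th, m, s, w)
    if (is.finite(obj) && obj < best_obj) {
      best_obj <- obj
      best <- th
    }
  }
  # quasi-Newton polish with the analytic gradient: LM can terminate early
  # in the flat a-b valley of this objective
  if (!is.null(best)) {
    grad_fn <- function(theta) {
      mb <- m^theta[2]
      r <- s - (theta[1] * mb + theta[3])
      c(-2 * sum(w * r * mb),
        -2 * sum(w * r * theta[1] * mb * log(m)),
        -2 * sum(w * r))
    }
    pol <- tryCatch(
      suppressWarnings(
        stats::optim(best, function(th) powerlaw_objective(th, m, s, w),
                     gr = grad_fn, method = "L-BFGS-B",
                     lower = lower + c(0, 0, 0), upper = pmin(upper, 1e15),
                     control = list(factr = 1e1, maxit = 500))),
      error = function(e) NULL)
    if (!is.null(pol) && is.finite(pol$value) && pol$value < best_obj) {
      best_obj <- pol$value
      best <- pol$par
    }
  }

  converged <- !is.null(best)
  if (!converged) {
    gs <- powerlaw_grid_search(m, s, w)
    best <- gs$theta
    best_obj <- gs$objective
  }
  # clamp into the open box so the constructor accepts boundary solutions
  a_hat <- max(best[1], 1e-12)
  b_hat <- min(max(best[2], -1 + 1e-12), -1e-12)
  c_hat <- max(best[3], 0)
  params <- powerlaw_params(a_hat, b_hat, c_hat)
  gof <- goodness_of_fit(m, s, params)

  structure(list(params = params, sizes = m, m_K = m_K, weights = w,
                 objective = best_obj, mae_fit = gof$mae_fit,
                 r2_fit = gof$r2_fit, r2_defined = gof$r2_defined,
                 converged = converged),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("power-law fit over %d sizes in [%s, %s]%s\n",
              length(x$sizes), format(min(x$sizes)), format(max(x$sizes)),
              if (x$converged) "" else "  [NOT converged; grid fallback]"))
  print(x$params)
  cat(sprintf("  MAE_fit = %.3g, R2_fit = %s\n", x$mae_fit,
              if (isTRUE(x$r2_defined)) sprintf("%.6f", x$r2_fit) else "undefined"))
  invisible(x)
}

#' Goodness of fit of a power-law curve against observed scores
#'
#' `MAE_fit` is the mean absolute residual between the observed scores and
#' the fitted curve; `R2_fit` is the coefficient of determination
#' `1 - SS_res / SS_tot` over the observed scores.
#'
#' @param sizes Positive training sizes (>= 2 points).
#' @param observed Observed scores at those sizes.
#' @param params Fitted [powerlaw_params()].
#'
#' @return List with `mae_fit`, `r2_fit` and `r2_defined` (`FALSE` when the
#'   observed scores have zero variance, in which case `r2_fit` is `NA`).
#' @export
goodness_of_fit <- function(sizes, observed, params) {
  stopifnot(length(sizes) == length(observed), length(sizes) >= 2)
  fitted <- powerlaw_eval(params, sizes)
  resid <- observed - fitted
  mae_fit <- mean(abs(resid))
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    list(mae_fit = mae_fit, r2_fit = NA_real_, r2_defined = FALSE)
  } else {
    list(mae_fit = mae_fit, r2_fit = 1 - sum(resid^2) / ss_tot, r2_defined = TRUE)
  }
}

#' Fit the power law separately to each data split
#'
#' Truncates the small-data region at `m_kmin`, then fits the weighted
#' power law independently to each split's scores (duplicate sizes within a
#' split are averaged first). Splits left with fewer than 4 distinct sizes
#' are skipped with a warning.
#'
#' @param raw Raw learning-curve score table (columns `split`, `train_size`,
#'   `score`).
#' @param m_kmin Small-data truncation size; see [truncate_small_data()].
#'
#' @return Named list of `"powerlaw_fit"` objects, one per retained split
#'   (names are the split indices).
#' @export
fit_per_split <- function(raw, m_kmin = 0) {
  raw <- truncate_small_data(raw, m_kmin)
  raw <- raw[is.finite(raw$score), , drop = FALSE]
  splits <- sort(unique(raw$split))
  fits <- list()
  for (n in splits) {
    sub <- raw[raw$split == n, , drop = FALSE]
    agg <- stats::aggregate(score ~ train_size, data = sub, FUN = mean)
    if (nrow(agg) < 4) {
      warning(sprintf("split %s skipped: only %d distinct sizes after truncation",
                      format(n), nrow(agg)))
      next
    }
    fits[[as.character(n)]] <- fit_powerlaw_weighted(agg$train_size, agg$score)
  }
  if (length(fits) == 0) stop("no split had enough sizes to fit")
  fits
}

#' Build quantile learning curves across per-split fits
#'
#' Evaluates every per-split fitted curve at each training size, takes
#' pointwise quantiles across splits (by default the 0.1, 0.5 and 0.9
#' quantiles, with linear interpolation between order statistics), and
#' refits the weighted power law to each quantile series. The refit of the
#' median series is the central learning curve; the 0.1/0.9 refits bound
#' its variability band.
#'
#' @param per_split_fits List of `"powerlaw_fit"` objects from
#'   [fit_per_split()].
#' @param sizes Training sizes at which to evaluate the curves (within the
#'   fitted range).
#' @param probabilities Quantile probabilities; must include 0.5. Default
#'   `c(0.1, 0.5, 0.9)`.
#'
#' @return Object of class `"quantile_curves"`: list with `sizes`, `values`
#'   (splits x sizes matrix of evaluated curves), `quantiles` (data frame
#'   `size`, one column per probability), and `fits` (named list of
#'   refitted `"powerlaw_fit"`, names like `"q0.1"`, `"q0.5"`, `"q0.9"`;
#'   `central` aliases the 0.5 refit).
#' @export
build_quantile_curves <- function(per_split_fits, sizes,
                                  probabilities = c(0.1, 0.5, 0.9)) {
  stopifnot(length(per_split_fits) >= 1, length(sizes) >= 4)
  if (!any(probabilities == 0.5))
    stop("'probabilities' must include 0.5 (the central curve)")
  probabilities <- sort(probabilities)
  sizes <- sort(unique(as.numeric(sizes)))
  values <- t(vapply(per_split_fits,
                     function(f) powerlaw_eval(f$params, sizes),
                     numeric(length(sizes))))
  qmat <- apply(values, 2, stats::quantile, probs = probabilities,
                names = FALSE, type = 7)
  qmat <- matrix(qmat, nrow = length(probabilities))
  qnames <- paste0("q", probabilities)
  quantiles <- data.frame(size = sizes, t(qmat))
  names(quantiles) <- c("size", qnames)
  fits <- lapply(seq_along(probabilities), function(i)
    fit_powerlaw_weighted(sizes, qmat[i, ]))
  names(fits) <- qnames
  fits$central <- fits[["q0.5"]]
  structure(list(sizes = sizes, values = values, probabilities = probabilities,
                 quantiles = quantiles, fits = fits),
            class = "quantile_curves")
}

#' @export
print.quantile_curves <- function(x, ...) {
  cat(sprintf("quantile learning curves over %d splits at %d sizes (probs: %s)\n",
              nrow(x$values), length(x$sizes),
              paste(x$probabilities, collapse = ", ")))
  cat("central fit:\n")
  print(x$fits$central)
  invisible(x)
}
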