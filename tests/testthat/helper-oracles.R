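# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: brute-force loops and grid enumeration, no shared code
# with the fitting path.

# Elementwise mean absolute error via an explicit loop.
oracle_mae <- function(pred, actual) {
  total <- 0
  for (i in seq_along(pred)) total <- total + abs(pred[i] - actual[i])
  total / length(pred)
}

# Weighted power-law objective at a parameter triple.
oracle_objective <- function(theta, m, s, w) {
  tot <- 0
  for (k in seq_along(m))
    tot <- tot + w[k] * (s[k] - (theta[1] * m[k]^theta[2] + theta[3]))^2
  tot
}

# Best objective over an n^3 bounded parameter grid (a log-spaced, b and c
# linear), mirroring the fit's constraint box.
oracle_grid_best <- function(m, s, w, n = 20) {
  a_grid <- exp(seq(log(0.05 * max(s)), log(50 * max(s)), length.out = n))
  b_grid <- seq(-0.95, -0.05, length.out = n)
  # same constraint box as the fit: 0 <= c < min(s) (empty when min(s) <= 0)
  c_grid <- if (min(s) > 0) seq(0, min(s) * 0.999, length.out = n) else 0
  best <- Inf
  for (a in a_grid) for (b in b_grid) for (cc in c_grid) {
    obj <- oracle_objective(c(a, b, cc), m, s, w)
    if (obj < best) best <- obj
  }
  best
}

# Quantile by hand: sort and linearly interpolate between order statistics
# (the type-7 definition).
oracle_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Trapezoid AUC of a Hill curve on an arbitrary-resolution log10-dose grid.
oracle_hill_auc <- function(hill, dose_range = c(1e-10, 1e-4), n = 6001) {
  lx <- seq(log10(dose_range[1]), log10(dose_range[2]), length.out = n)
  v <- hill$E_inf + (1 - hill$E_inf) / (1 + (10^lx / hill$EC50)^hill$H)
  sum(diff(lx) * (v[-1] + v[-n]) / 2) / (lx[n] - lx[1])
}
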