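#' Three-parameter Hill-slope dose-response parameters
#'
#' Viability as a function of dose follows the sigmoid
#' \deqn{v(d) = E_{inf} + \frac{1 - E_{inf}}{1 + (d / EC_{50})^{H}},}
#' with the untreated viability (upper asymptote) fixed at 1. `E_inf` is
#' the viability floor at saturating dose, `EC50` the dose of half-maximal
#' effect, and `H` the Hill slope (steepness).
#'
#' @param E_inf Lower asymptote, in `[0, 1]`.
#' @param EC50 Half-effect dose, molar, positive.
#' @param H Hill slope, positive.
#' @return Object of class `"hill_params"`.
#' @export
hill_params <- function(E_inf, EC50, H) {
  stopifnot(length(E_inf) == 1, length(EC50) == 1, length(H) == 1)
  if (!is.finite(E_inf) || E_inf < 0 || E_inf > 1) stop("E_inf must be in [0, 1]")
  if (!is.finite(EC50) || EC50 <= 0) stop("EC50 must be a positive concentration")
  if (!is.finite(H) || H <= 0) stop("H must be positive")
  structure(list(E_inf = E_inf, EC50 = EC50, H = H), class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill curve: E_inf = %.4g, EC50 = %.4g M, H = %.4g\n",
              x$E_inf, x$EC50, x$H))
  invisible(x)
}

#' Evaluate a Hill viability curve
#'
#' @param hill A [hill_params()] object.
#' @param dose Vector of positive molar doses.
#' @return Viability fractions in `[E_inf, 1]`.
#' @examples
#' h <- hill_params(E_inf = 0.2, EC50 = 1e-7, H = 1)
#' hill_eval(h, 1e-7)  # midpoint: 0.6
#' @export
hill_eval <- function(hill, dose) {
  if (any(!is.finite(dose)) || any(dose <= 0)) stop("doses must be positive")
  hill$E_inf + (1 - hill$E_inf) / (1 + (dose / hill$EC50)^hill$H)
}

#' Fit the Hill-slope model to measured viabilities
#'
#' Least-squares fit of [hill_eval()] in log10-dose space by bounded
#' Levenberg-Marquardt. Initialization puts `EC50` at the median log-dose,
#' `H = 1` and `E_inf` at the minimum observed viability clipped to
#' `[0, 1]`; four fallback starts vary the initial EC50 and slope. Bounds:
#' `E_inf` in `[0, 1]`, log10(EC50) within 3 decades of the measured dose
#' range, `H` in `[1e-3, 100]`.
#'
#' @param doses Vector of positive molar doses (>= 3 points).
#' @param viabilities Measured viability fractions, same length.
#' @return List with `hill` ([hill_params()]), `r2_dose`
#'   (`1 - SS_res/SS_tot`; `NA` when the viabilities have zero variance)
#'   and `r2_defined`. A zero-variance input returns the flat fit
#'   (`E_inf` at that constant level if it is within `[0, 1]`).
#' @export
fit_hill <- function(doses, viabilities) {
  stopifnot(length(doses) == length(viabilities), length(doses) >= 3)
  if (any(doses <= 0)) stop("doses must be positive")
  if (any(!is.finite(viabilities))) stop("viabilities must be finite")
  ld <- log10(doses)
  v <- as.numeric(viabilities)
  ss_tot <- sum((v - mean(v))^2)

  lower <- c(E_inf = 0, lec50 = min(ld) - 3, H = 1e-3)
  upper <- c(E_inf = 1, lec50 = max(ld) + 3, H = 100)
  model <- function(th, x) th[1] + (1 - th[1]) / (1 + 10^(th[3] * (x - th[2])))
  resid_fn <- function(th) v - model(th, ld)

  e0 <- min(max(min(v), 0), 1)
  starts <- list(c(e0, stats::median(ld), 1),
                 c(e0, stats::median(ld), 3),
                 c(e0, min(ld), 1),
                 c(e0, max(ld), 1),
                 c(0,  mean(range(ld)), 0.5))
  best <- NULL
  best_ss <- Inf
  for (th0 in starts) {
    th0 <- pmin(pmax(th0, lower), upper)
    res <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    ss <- sum(resid_fn(res$par)^2)
    if (is.finite(ss) && ss < best_ss) {
      best_ss <- ss
      best <- res$par
    }
    if (best_ss < 1e-20 || (ss_tot > 0 && best_ss / ss_tot < 1e-12)) break
  }
  if (is.null(best)) stop("Hill fit failed to converge from all starts")
  hill <- hill_params(E_inf = min(max(best[1], 0), 1),
                      EC50 = 10^best[2], H = max(best[3], 1e-3))
  if (ss_tot == 0) {
    # a flat curve at level v: put EC50 far below the measured range with a
    # steep slope, so the sigmoid sits at its E_inf plateau everywhere
    flat <- hill_params(E_inf = min(max(v[1], 0), 1),
                        EC50 = min(doses) * 1e-4, H = 3)
    return(list(hill = flat, r2_dose = NA_real_, r2_defined = FALSE))
  }
  list(hill = hill, r2_dose = 1 - best_ss / ss_tot, r2_defined = TRUE)
}

#' Dose-range normalized AUC of a Hill curve
#'
#' Integrates the fitted viability curve over log10-dose across the assay
#' dose range (default `[1e-10, 1e-4]` M) by the composite trapezoid rule
#' on a uniform log10-dose grid, and divides by the range width (6 decades
#' by default) so the value lies in `[0, 1]`. Lower AUC means stronger
#' growth inhibition.
#'
#' @param hill A [hill_params()] object.
#' @param dose_range Length-2 positive molar range (default
#'   `c(1e-10, 1e-4)`).
#' @param n_grid Number of trapezoid grid points (default 601).
#' @return AUC in `[E_inf, 1]`.
#' @examples
#' compute_auc(hill_params(0, 1e-7, 2))  # 0.5: EC50 centered in the range
#' @export
compute_auc <- function(hill, dose_range = c(1e-10, 1e-4), n_grid = 601) {
  stopifnot(length(dose_range) == 2, all(dose_range > 0),
            dose_range[2] > dose_range[1], n_grid >= 3)
  lx <- seq(log10(dose_range[1]), log10(dose_range[2]), length.out = n_grid)
  vy <- hill_eval(hill, 10^lx)
  pracma::trapz(lx, vy) / (lx[n_grid] - lx[1])
}

#' Fit and label a table of raw viability measurements
#'
#' Groups a raw measurement table by cell-drug pair, fits the Hill-slope
#' model to each pair's dose-viability points, computes the normalized AUC
#' from the fitted curve, and marks whether the pair passes the fit-quality
#' filter (`r2_dose >= r2_min`). Pairs with fewer than 3 doses are dropped
#' with a warning.
#'
#' @param measurements Data frame with columns `cell_id`, `drug_id`,
#'   `dose_M`, `viability` (one row per measured dose).
#' @param r2_min Fit-quality threshold (default 0.3).
#' @inheritParams compute_auc
#' @return Data frame with one row per cell-drug pair: `cell_id`,
#'   `drug_id`, `E_inf`, `EC50`, `H`, `r2_dose`, `auc`, `passed_filter`.
#'   `auc` is `NA` for pairs failing the filter.
#' @export
process_dose_response <- function(measurements, r2_min = 0.3,
                                  dose_range = c(1e-10, 1e-4)) {
  need <- c("cell_id", "drug_id", "dose_M", "viability")
  if (!all(need %in% names(measurements)))
    stop("measurements need columns: ", paste(need, collapse = ", "))
  keys <- interaction(measurements$cell_id, measurements$drug_id, drop = TRUE)
  groups <- split(measurements, keys)
  too_few <- vapply(groups, nrow, 0L) < 3
  if (any(too_few)) {
    warning(sprintf("%d cell-drug pair(s) dropped: fewer than 3 dose points",
                    sum(too_few)))
    groups <- groups[!too_few]
  }
  rows <- lapply(groups, function(g) {
    fit <- fit_hill(g$dose_M, g$viability)
    r2 <- if (fit$r2_defined) fit$r2_dose else -Inf
    passed <- r2 >= r2_min
    data.frame(cell_id = g$cell_id[1], drug_id = g$drug_id[1],
               E_inf = fit$hill$E_inf, EC50 = fit$hill$EC50, H = fit$hill$H,
               r2_dose = fit$r2_dose,
               auc = if (passed) compute_auc(fit$hill, dose_range) else NA_real_,
               passed_filter = passed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter dose-response records by fit quality
#'
#' Retains exactly the records whose dose-curve fit reached
#' `r2_dose >= r2_min`; the boundary value is kept ("lower than" read
#' strictly). The number of removals is attached as attribute `n_removed`
#' and reported via a message.
#'
#' @param records Data frame carrying an `r2_dose` column (e.g. from
#'   [process_dose_response()]).
#' @param r2_min Threshold (default 0.3).
#' @return The retained records, with attribute `n_removed`.
#' @export
filter_records <- function(records, r2_min = 0.3) {
  stopifnot(is.data.frame(records))
  if (nrow(records) > 0 && !"r2_dose" %in% names(records))
    stop("records must carry an 'r2_dose' column")
  keep <- if (nrow(records) == 0) logical(0)
          else !is.na(records$r2_dose) & records$r2_dose >= r2_min
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  n_removed <- nrow(records) - nrow(out)
  message(sprintf("filter_records: removed %d of %d record(s) with r2_dose < %s",
                  n_removed, nrow(records), format(r2_min)))
  attr(out, "n_removed") <- n_removed
  out
}

#' Read / write dose-response tables
#'
#' Raw measurement tables are tab-delimited text with header
#' `cell_id  drug_id  dose_M  viability`; processed record tables add the
#' fitted parameters and AUC columns.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return `read_dose_table()` returns a data frame; the writers return
#'   `path` invisibly.
#' @export
read_dose_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_dose_table
#' @export
write_dose_table <- function(x, path) {
  write_delim_precise(x, path)
}
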