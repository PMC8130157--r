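#' Forecast the error score at a hypothetical training size
#'
#' Evaluates a fitted learning curve at training size `m` and reports the
#' percentage reduction relative to the score at the full training size
#' `m_K` carried by the fit -- e.g. "what error do we expect if the
#' training set is doubled?".
#'
#' @param fit A `"powerlaw_fit"` (typically the central-curve fit).
#' @param m Positive training size to query (may exceed the fitted range).
#' @param m_K Reference full training size; defaults to the largest fitted
#'   size.
#' @return List with `score`, `y_K` (score at `m_K`) and `reduction_pct`
#'   (`100 * (y_K - score) / y_K`).
#' @export
score_at_size <- function(fit, m, m_K = fit$m_K) {
  stopifnot(inherits(fit, "powerlaw_fit"), m > 0, m_K > 0)
  y_K <- powerlaw_eval(fit$params, m_K)
  score <- powerlaw_eval(fit$params, m)
  list(score = score, y_K = y_K, reduction_pct = 100 * (y_K - score) / y_K)
}

#' Training size required to reach a target error score
#'
#' Closed-form inversion of the power law:
#' `m = ((target - c) / a)^(1/b)`. Targets at or below the irreducible
#' error `c` are unreachable at any training size; those raise an error of
#' class `"lcpower_unreachable"`.
#'
#' @param fit A `"powerlaw_fit"`.
#' @param target_score Desired error score, strictly above the fitted `c`.
#' @return The (real-valued) required training size.
#' @export
size_for_score <- function(fit, target_score) {
  stopifnot(inherits(fit, "powerlaw_fit"), length(target_score) == 1)
  p <- fit$params
  if (target_score <= p$c)
    stop(structure(class = c("lcpower_unreachable", "error", "condition"),
                   list(message = sprintf(
                     "unreachable: target score %.6g is at or below the irreducible error plateau c = %.6g",
                     target_score, p$c), call = sys.call(-1))))
  ((target_score - p$c) / p$a)^(1 / p$b)
}

#' Relative change in error score versus a baseline model
#'
#' Returns the signed percentage `100 * (y_model - y_baseline) /
#' y_baseline`: negative when the model improves on the baseline. Report
#' layers conventionally present the magnitude as "improvement".
#'
#' @param y_model,y_baseline Error scores; `y_baseline` must be positive.
#' @return Signed percentage.
#' @examples
#' delta_improvement(0.09, 0.10)  # -10: a 10% improvement
#' @export
delta_improvement <- function(y_model, y_baseline) {
  if (any(y_baseline <= 0)) stop("baseline score must be positive")
  100 * (y_model - y_baseline) / y_baseline
}

#' Required-size factor relative to the full training size
#'
#' The multiple of the current training-set size needed to reach a target
#' score, reported to one decimal as in forecast tables.
#'
#' @param required_size Forecast training size.
#' @param train_size Current full training size `|T|`.
#' @return `round(required_size / train_size, 1)`.
#' @examples
#' size_factor(649056, 115863)  # 5.6
#' @export
size_factor <- function(required_size, train_size) {
  stopifnot(all(train_size > 0))
  round(required_size / train_size, 1)
}

#' Build a forecast comparison report across models
#'
#' Assembles, for each model's central-curve fit: the error at the full
#' training size (`y_K`); the signed percent change versus the baseline
#' model (`delta_pct`, `NA` for the baseline itself, rendered as a
#' positive "improvement" when negative); the forecast error if the
#' training size is doubled, with its percent reduction; and the training
#' size required to cut the error by 10% (`target = 0.9 * y_K`), with the
#' size factor relative to `|T|`. When a model's entry also carries
#' `lower`/`upper` quantile-curve fits, interval columns `y_K_lo`/`y_K_hi`
#' are included.
#'
#' @param fits Named list: one entry per model, each either a
#'   `"powerlaw_fit"` (the central fit) or a list with elements `central`
#'   and optionally `lower`, `upper`.
#' @param baseline_id Name of the baseline model in `fits`.
#' @param m_K Full training size `|T|`; defaults to the baseline fit's
#'   largest size.
#' @return Data frame of class `"forecast_report"` with columns `model`,
#'   `train_size`, `y_K`, `delta_pct`, `y_at_2T`, `reduction_pct`,
#'   `size_for_90pct`, `size_factor` (and interval columns when supplied).
#'   Percentages are rounded to two decimals, factors to one.
#' @export
build_report <- function(fits, baseline_id, m_K = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1, !is.null(names(fits)))
  if (!baseline_id %in% names(fits))
    stop("baseline '", baseline_id, "' is not among the fitted models")
  get_central <- function(f) if (inherits(f, "powerlaw_fit")) f else f$central
  base_fit <- get_central(fits[[baseline_id]])
  if (is.null(m_K)) m_K <- base_fit$m_K
  y_base <- powerlaw_eval(base_fit$params, m_K)
  has_band <- any(vapply(fits, function(f)
    !inherits(f, "powerlaw_fit") && !is.null(f$lower) && !is.null(f$upper),
    logical(1)))
  rows <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    central <- get_central(f)
    y_K <- powerlaw_eval(central$params, m_K)
    at2 <- score_at_size(central, 2 * m_K, m_K = m_K)
    req <- tryCatch(size_for_score(central, 0.9 * y_K),
                    lcpower_unreachable = function(e) NA_real_)
    row <- data.frame(
      model = id, train_size = m_K, y_K = y_K,
      delta_pct = if (id == baseline_id) NA_real_
                  else round(delta_improvement(y_K, y_base), 2),
      y_at_2T = at2$score,
      reduction_pct = round(at2$reduction_pct, 2),
      size_for_90pct = req,
      size_factor = if (is.na(req)) NA_real_ else size_factor(req, m_K))
    if (has_band) {
      row$y_K_lo <- if (!inherits(f, "powerlaw_fit") && !is.null(f$lower))
        powerlaw_eval(f$lower$params, m_K) else NA_real_
      row$y_K_hi <- if (!inherits(f, "powerlaw_fit") && !is.null(f$upper))
        powerlaw_eval(f$upper$params, m_K) else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("forecast_report", "data.frame")
  out
}

#' @export
print.forecast_report <- function(x, ...) {
  cat("forecast report (baseline delta_pct is NA; negative delta = improvement):\n")
  print.data.frame(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Read / write forecast reports
#'
#' @param x A `"forecast_report"` data frame.
#' @param path File path (tab-delimited text; `.json` extension writes
#'   JSON).
#' @return `read_report()` returns the report; the writer returns `path`
#'   invisibly.
#' @export
write_report <- function(x, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(x), path, digits = NA, na = "null",
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
  } else {
    write_delim_precise(as.data.frame(x), path)
  }
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  df <- if (grepl("\\.json$", path))
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  else utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  class(df) <- c("forecast_report", "data.frame")
  df
}
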