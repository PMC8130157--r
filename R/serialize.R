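# Tab-delimited writer that keeps doubles decimal-faithful (%.17g survives
# a read round-trip bit-exactly).
write_delim_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Serialize a split plan to JSON and back
#'
#' A plan file records the seed, fractions and every index array, so a run
#' is exactly resumable from the file alone.
#'
#' @param plan A [make_splits()] plan.
#' @param path File path.
#' @return `read_split_plan()` returns the `"split_plan"`; the writer
#'   returns `path` invisibly.
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  jsonlite::write_json(unclass(plan), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                    simplifyDataFrame = FALSE),
                error = function(e)
                  stop("corrupted split-plan file '", path, "': ",
                       conditionMessage(e)))
  need <- c("n_samples", "n_splits", "fractions", "base_seed", "splits")
  if (!all(need %in% names(x)))
    stop("corrupted split-plan file '", path, "': missing field(s) ",
         paste(setdiff(need, names(x)), collapse = ", "))
  x$splits <- lapply(x$splits, function(s)
    list(train = as.integer(s$train), val = as.integer(s$val),
         test = as.integer(s$test)))
  x$n_samples <- as.integer(x$n_samples)
  x$n_splits <- as.integer(x$n_splits)
  x$base_seed <- as.integer(x$base_seed)
  structure(x, class = "split_plan")
}

#' Serialize a power-law fit to JSON and back
#'
#' Numeric fields survive the round trip bit-faithfully (full-precision
#' JSON serialization).
#'
#' @param fit A `"powerlaw_fit"`.
#' @param path File path.
#' @return `read_fit()` returns the `"powerlaw_fit"`; the writer returns
#'   `path` invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "powerlaw_fit"))
  x <- unclass(fit)
  x$params <- unclass(x$params)
  # I(17) significant digits keeps doubles bit-faithful across the trip
  jsonlite::write_json(x, path, digits = I(17), auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e)
                  stop("corrupted fit file '", path, "': ",
                       conditionMessage(e)))
  need <- c("params", "sizes", "m_K", "weights")
  if (!all(need %in% names(x)))
    stop("corrupted fit file '", path, "': missing field(s) ",
         paste(setdiff(need, names(x)), collapse = ", "))
  x$params <- powerlaw_params(as.numeric(x$params$a), as.numeric(x$params$b),
                              as.numeric(x$params$c))
  for (f in c("sizes", "m_K", "weights", "objective", "mae_fit", "r2_fit"))
    if (!is.null(x[[f]])) x[[f]] <- as.numeric(x[[f]])
  if (is.null(x$r2_fit)) x$r2_fit <- NA_real_
  structure(x, class = "powerlaw_fit")
}

#' Write quantile-curve fits and the per-size quantile table
#'
#' Writes a JSON file mapping each quantile to its refitted parameters and
#' goodness of fit, plus (optionally) a delimited per-size table with the
#' quantile series and their fitted values.
#'
#' @param curves A [build_quantile_curves()] result.
#' @param path JSON output path.
#' @param table_path Optional path for the per-size delimited table.
#' @return `path`, invisibly.
#' @export
write_quantile_fits <- function(curves, path, table_path = NULL) {
  stopifnot(inherits(curves, "quantile_curves"))
  qn <- paste0("q", curves$probabilities)
  fits <- lapply(curves$fits[qn], function(f)
    list(a = f$params$a, b = f$params$b, c = f$params$c,
         mae_fit = f$mae_fit, r2_fit = f$r2_fit, converged = f$converged))
  jsonlite::write_json(fits, path, digits = NA, auto_unbox = TRUE, na = "null")
  if (!is.null(table_path)) {
    tab <- curves$quantiles
    for (q in qn)
      tab[[paste0("fitted_", q)]] <- powerlaw_eval(curves$fits[[q]]$params,
                                                   tab$size)
    write_delim_precise(tab, table_path)
  }
  invisible(path)
}

#' Write / read a response dataset as delimited text
#'
#' Header row: `sample_id, cell_id, drug_id, ge_1..ge_C, dd_1..dd_D,
#' response`.
#'
#' @param dataset A [gen_response_dataset()]-style data frame.
#' @param path File path.
#' @return `read_response_dataset()` returns the dataset; the writer
#'   returns `path` invisibly.
#' @export
write_response_dataset <- function(dataset, path) {
  write_delim_precise(as.data.frame(dataset), path)
}

#' @rdname write_response_dataset
#' @export
read_response_dataset <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"response" %in% names(df) ||
      length(grep("^(ge|dd)_", names(df))) == 0)
    stop("not a response-dataset file: '", path, "'")
  class(df) <- c("response_dataset", "data.frame")
  df
}
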