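#' Validate a pipeline run configuration
#'
#' Parses a YAML or JSON configuration (file path, literal text, or an
#' already-parsed list), rejects unknown keys (typo protection), applies
#' documented defaults, and checks every field's range. The returned
#' object drives [run_pipeline()].
#'
#' Recognized keys and defaults:
#' \describe{
#'   \item{`dataset`}{path to a delimited response-dataset file; mutually
#'     exclusive with `synthetic`.}
#'   \item{`synthetic`}{list of [gen_response_dataset()] arguments
#'     (`n_cells`, `n_drugs`, `n_cell_features`, `n_drug_features`,
#'     `noise_sd`).}
#'   \item{`estimator`}{required; a [builtin_estimators()] name.}
#'   \item{`n_splits`}{N, default 20.}
#'   \item{`K`}{default 10.}
#'   \item{`m_min`, `spacing`}{schedule controls; defaults `NULL` (auto)
#'     and `"log"`.}
#'   \item{`fractions`}{default `c(0.8, 0.1, 0.1)`.}
#'   \item{`patience`}{default 50.}
#'   \item{`metric`}{default `"mae"`.}
#'   \item{`base_seed`}{default 0.}
#'   \item{`m_kmin`}{small-data truncation for fitting, default 0.}
#'   \item{`probabilities`}{default `c(0.1, 0.5, 0.9)`.}
#'   \item{`output_dir`}{optional artifact directory.}
#' }
#'
#' @param config A file path, a YAML/JSON string, or a list.
#' @return A validated `"run_config"` list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (file.exists(config)) yaml::read_yaml(config)
              else yaml::yaml.load(config)
  }
  if (!is.list(config)) stop("config must be a file path, YAML/JSON text, or a list")
  known <- c("dataset", "synthetic", "estimator", "n_splits", "K", "m_min",
             "spacing", "fractions", "patience", "metric", "base_seed",
             "m_kmin", "probabilities", "output_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(n_splits = 20, K = 10, m_min = NULL, spacing = "log",
                   fractions = c(0.8, 0.1, 0.1), patience = 50,
                   metric = "mae", base_seed = 0, m_kmin = 0,
                   probabilities = c(0.1, 0.5, 0.9), output_dir = NULL)
  for (key in names(defaults))
    if (is.null(config[[key]])) config[[key]] <- defaults[[key]]

  fail <- function(field, msg) stop(sprintf("config field '%s': %s", field, msg))
  if (is.null(config$estimator)) fail("estimator", "is required")
  if (is.null(config$dataset) == is.null(config$synthetic))
    fail("dataset", "exactly one of 'dataset' or 'synthetic' must be given")
  if (!is.null(config$dataset) && !file.exists(config$dataset))
    fail("dataset", sprintf("path '%s' not resolvable", config$dataset))
  if (config$n_splits < 1) fail("n_splits", "must be >= 1")
  if (config$K < 1) fail("K", "must be >= 1")
  fr <- config$fractions
  if (length(fr) != 3 || any(fr <= 0) || abs(sum(fr) - 1) > 1e-9)
    fail("fractions", "must be 3 positive numbers summing to 1")
  if (!config$spacing %in% c("log", "linear", "explicit"))
    fail("spacing", "must be log, linear or explicit")
  if (!identical(config$metric, "mae")) fail("metric", "only 'mae' is registered")
  if (config$m_kmin < 0) fail("m_kmin", "must be >= 0")
  if (config$patience <= 0) fail("patience", "must be positive (Inf allowed)")
  pr <- config$probabilities
  if (any(pr <= 0) || any(pr >= 1) || !any(pr == 0.5))
    fail("probabilities", "must lie in (0,1) and include 0.5")
  structure(config, class = "run_config")
}

#' Run the full learning-curve pipeline
#'
#' Executes the end-to-end workflow described by a validated configuration:
#' load (or synthesize) the response dataset, build the shuffled splits and
#' the nested subset schedule, train N x K models and collect raw scores,
#' fit the power law per split, build and refit the quantile curves, and
#' assemble the forecast report. Running the stages individually with the
#' same configuration gives an identical final report.
#'
#' When `output_dir` is set, all artifacts are written there
#' (`plan.json`, `lc_scores.tsv`, `fits.json`, `quantile_table.tsv`,
#' `report.tsv`, `report.json`) together with a `run_log.json` recording
#' every seed and the realized size schedule.
#'
#' @param config A `"run_config"` (or anything [validate_config()] accepts).
#' @param verbose Forward per-task progress messages from the runner.
#' @return List with `dataset`, `plan`, `schedule`, `raw`, `per_split_fits`,
#'   `curves`, `report`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  config <- validate_config(config)
  dataset <- if (!is.null(config$dataset)) read_response_dataset(config$dataset)
  else do.call(gen_response_dataset,
               c(config$synthetic, list(seed = config$base_seed)))
  plan <- make_splits(nrow(dataset), n_splits = config$n_splits,
                      fractions = config$fractions,
                      base_seed = config$base_seed)
  schedule <- make_schedule(plan$train_size, K = config$K,
                            m_min = config$m_min, spacing = config$spacing)
  estimator <- builtin_estimators(config$estimator)
  raw <- run_learning_curve(dataset, plan, schedule, estimator,
                            metric = config$metric, patience = config$patience,
                            dataset_id = if (!is.null(config$dataset))
                              basename(config$dataset) else "synthetic",
                            verbose = verbose)
  per_split <- fit_per_split(raw, m_kmin = config$m_kmin)
  fit_sizes <- sort(unique(raw$train_size[raw$train_size >= config$m_kmin]))
  curves <- build_quantile_curves(per_split, fit_sizes,
                                  probabilities = config$probabilities)
  qn <- paste0("q", sort(config$probabilities))
  fits_entry <- list(central = curves$fits$central,
                     lower = curves$fits[[qn[1]]],
                     upper = curves$fits[[qn[length(qn)]]])
  fits_map <- stats::setNames(list(fits_entry), estimator$id)
  report <- build_report(fits_map, baseline_id = estimator$id,
                         m_K = plan$train_size)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$output_dir, f)
    write_split_plan(plan, p("plan.json"))
    write_lc_scores(raw, p("lc_scores.tsv"))
    write_quantile_fits(curves, p("fits.json"), p("quantile_table.tsv"))
    write_report(report, p("report.tsv"))
    write_report(report, p("report.json"))
    jsonlite::write_json(
      list(base_seed = config$base_seed,
           split_seeds = config$base_seed + seq_len(config$n_splits),
           n_samples = plan$n_samples, fractions = config$fractions,
           schedule = schedule$sizes, realized_k = schedule$realized_k,
           estimator = estimator$id, metric = config$metric,
           patience = config$patience, m_kmin = config$m_kmin),
      p("run_log.json"), digits = NA, auto_unbox = TRUE)
  }
  list(dataset = dataset, plan = plan, schedule = schedule, raw = raw,
       per_split_fits = per_split, curves = curves, report = report)
}
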