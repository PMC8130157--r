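#' Generate learning-curve scores from a known power law
#'
#' Draws the raw N x K score table that a learning-curve run would produce,
#' but from a known generating curve `s(m) = a*m^b + c` plus additive
#' Gaussian noise. The noise standard deviation at size `m` is
#' `noise_sd0 * sqrt(m_K / m)` -- score spread shrinks as the training size
#' grows, the simplest monotone stand-in for the larger spread real runs
#' show at small sizes (the true cross-split noise structure is not
#' characterized, so this model is a configurable stand-in). Split `n`
#' draws from seed `seed + n`, so adding splits never changes existing
#' ones.
#'
#' @param params Generating [powerlaw_params()].
#' @param sizes Strictly increasing vector of positive integer training sizes.
#' @param n_splits Number of splits N (>= 1).
#' @param noise_sd0 Score-scale noise SD at the largest size (>= 0).
#' @param seed Integer base seed.
#'
#' @return Raw learning-curve table (class `"lc_raw"`, a data frame) with
#'   columns `dataset_id`, `estimator_id`, `metric`, `split`, `subset`,
#'   `train_size`, `score`.
#' @examples
#' p <- powerlaw_params(1, -0.5, 0.05)
#' gen_powerlaw_scores(p, sizes = c(100, 400), n_splits = 1)$score  # 0.15 0.10
#' @export
gen_powerlaw_scores <- function(params, sizes, n_splits = 20,
                                noise_sd0 = 0, seed = 0) {
  stopifnot(length(sizes) >= 1, n_splits >= 1, noise_sd0 >= 0)
  sizes <- as.numeric(sizes)
  if (any(sizes < 1)) stop("all sizes must be >= 1")
  if (is.unsorted(sizes, strictly = TRUE)) stop("sizes must be strictly increasing")
  K <- length(sizes)
  m_K <- sizes[K]
  mu <- powerlaw_eval(params, sizes)
  sd_k <- noise_sd0 * sqrt(m_K / sizes)
  recs <- vector("list", n_splits)
  for (n in seq_len(n_splits)) {
    set.seed(as.integer(seed + n))
    eps <- if (noise_sd0 > 0) stats::rnorm(K, sd = sd_k) else numeric(K)
    recs[[n]] <- data.frame(split = n, subset = seq_len(K),
                            train_size = sizes, score = mu + eps)
  }
  out <- do.call(rbind, recs)
  new_lc_raw(out, dataset_id = "synthetic-powerlaw", estimator_id = "generator",
             metric = "mae")
}

#' Generate a synthetic cell-by-drug response dataset
#'
#' Emulates the cross design of cell-line drug screens: every cell line is
#' paired with every drug, so each cell's feature vector recurs across its
#' `n_drugs` samples (and symmetrically for drugs). The response is a
#' smooth bounded function of a rank-3 bilinear cell-drug interaction plus
#' additive Gaussian noise, squashed into `[0, 1]` by a logistic and then
#' remapped by a cube root so the marginal is right-skewed -- most
#' synthetic AUC values concentrate toward 1 (weak responses), as real
#' normalized dose-response AUC distributions do.
#'
#' @param n_cells,n_drugs Numbers of cell lines and drugs; the dataset has
#'   `n_cells * n_drugs` rows.
#' @param n_cell_features,n_drug_features Feature dimensions (defaults 20
#'   each; statistical stand-ins, not biological features).
#' @param noise_sd SD of the Gaussian noise added before squashing
#'   (default 0.25 on the latent scale).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#'
#' @return Data frame (class `"response_dataset"`) with columns
#'   `sample_id`, `cell_id`, `drug_id`, `ge_1..ge_C`, `dd_1..dd_D`,
#'   `response` (in `[0, 1]`).
#' @export
gen_response_dataset <- function(n_cells = 100, n_drugs = 100,
                                 n_cell_features = 20, n_drug_features = 20,
                                 noise_sd = 0.25, seed = 0) {
  stopifnot(n_cells >= 1, n_drugs >= 1, n_cell_features >= 1,
            n_drug_features >= 1, noise_sd >= 0)
  set.seed(as.integer(seed))
  rank <- 3
  Zc <- matrix(stats::rnorm(n_cells * n_cell_features), n_cells)
  Zd <- matrix(stats::rnorm(n_drugs * n_drug_features), n_drugs)
  Wc <- matrix(stats::rnorm(n_cell_features * rank), n_cell_features) /
    sqrt(n_cell_features)
  Wd <- matrix(stats::rnorm(n_drug_features * rank), n_drug_features) /
    sqrt(n_drug_features)
  U <- Zc %*% Wc                      # latent cell activities, n_cells x rank
  V <- Zd %*% Wd
  ci <- rep(seq_len(n_cells), each = n_drugs)
  di <- rep(seq_len(n_drugs), times = n_cells)
  eta <- 2 * rowSums(U[ci, , drop = FALSE] * V[di, , drop = FALSE]) / sqrt(rank)
  noise <- if (noise_sd > 0) stats::rnorm(length(eta), sd = noise_sd) else 0
  response <- stats::plogis(eta + noise)^(1 / 3)
  feat <- cbind(Zc[ci, , drop = FALSE], Zd[di, , drop = FALSE])
  colnames(feat) <- c(paste0("ge_", seq_len(n_cell_features)),
                      paste0("dd_", seq_len(n_drug_features)))
  out <- data.frame(sample_id = seq_along(eta),
                    cell_id = sprintf("cell_%03d", ci),
                    drug_id = sprintf("drug_%03d", di),
                    feat, response = response)
  class(out) <- c("response_dataset", "data.frame")
  out
}

#' Feature matrix and response vector of a response dataset
#'
#' @param dataset A [gen_response_dataset()] data frame (or any data frame
#'   whose feature columns start with `ge_` or `dd_` and whose label column
#'   is `response`).
#' @return `response_features()`: numeric matrix of the feature columns;
#'   `response_values()`: numeric response vector.
#' @export
response_features <- function(dataset) {
  cols <- grep("^(ge|dd)_", names(dataset), value = TRUE)
  if (length(cols) == 0) stop("no feature columns (ge_*/dd_*) found")
  as.matrix(dataset[, cols, drop = FALSE])
}

#' @rdname response_features
#' @export
response_values <- function(dataset) {
  if (!"response" %in% names(dataset)) stop("no 'response' column found")
  as.numeric(dataset$response)
}

#' Generate synthetic dose-response viability measurements
#'
#' Evaluates a Hill curve at the given molar doses and adds Gaussian noise,
#' giving a measured-viability table whose generating parameters are known
#' -- the inverse of [fit_hill()], used to validate the dose-response
#' pipeline.
#'
#' @param hill Generating [hill_params()].
#' @param doses Vector of positive molar concentrations.
#' @param noise_sd Gaussian noise SD on the viability scale (>= 0).
#' @param seed Integer seed.
#'
#' @return Data frame with columns `dose_M`, `viability`.
#' @export
gen_dose_response <- function(hill, doses, noise_sd = 0, seed = 0) {
  stopifnot(length(doses) >= 1, noise_sd >= 0)
  if (any(doses <= 0)) stop("doses must be positive molar concentrations")
  set.seed(as.integer(seed))
  v <- hill_eval(hill, doses)
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), sd = noise_sd)
  data.frame(dose_M = as.numeric(doses), viability = v)
}
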