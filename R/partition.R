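#' Shuffled train/validation/test splits
#'
#' Produces `n_splits` independent random partitions of `1:n_samples` into
#' disjoint training (T), validation (V) and test (E) sets. Shuffling the
#' sample order before cutting makes the three partitions likely to share a
#' similar response distribution. Split `n` shuffles with seed
#' `base_seed + n`, so extending the number of splits never changes
#' existing ones.
#'
#' Partition sizes are deterministic given `n_samples` and `fractions`:
#' V and E take the floor of their share and the remainder goes to T (which
#' keeps T the largest set, matching its 0.8 default share).
#'
#' @param n_samples Total number of samples (>= 10).
#' @param n_splits Number of independent splits N (default 20).
#' @param fractions Length-3 numeric `(train, val, test)`; positive, summing
#'   to 1 (default `c(0.8, 0.1, 0.1)`).
#' @param base_seed Integer base seed.
#'
#' @return Object of class `"split_plan"`: list with the call parameters and
#'   `splits`, a list of `n_splits` elements each holding integer index
#'   vectors `train` (in shuffled order -- nested subsets are prefixes of
#'   it), `val`, `test`.
#' @examples
#' plan <- make_splits(100, n_splits = 3, base_seed = 42)
#' lengths(plan$splits[[1]])
#' @export
make_splits <- function(n_samples, n_splits = 20,
                        fractions = c(0.8, 0.1, 0.1), base_seed = 0) {
  stopifnot(length(n_samples) == 1, n_samples >= 10,
            length(n_splits) == 1, n_splits >= 1,
            length(fractions) == 3)
  if (any(fractions <= 0)) stop("all three fractions must be positive")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n_samples <- as.integer(n_samples)
  n_val <- floor(fractions[2] * n_samples)
  n_test <- floor(fractions[3] * n_samples)
  n_train <- n_samples - n_val - n_test
  if (min(n_train, n_val, n_test) < 1)
    stop("each of T, V, E must receive at least one sample")
  splits <- vector("list", n_splits)
  for (n in seq_len(n_splits)) {
    set.seed(as.integer(base_seed + n))
    perm <- sample.int(n_samples)
    splits[[n]] <- list(
      train = perm[seq_len(n_train)],
      val   = perm[n_train + seq_len(n_val)],
      test  = perm[n_train + n_val + seq_len(n_test)])
  }
  structure(list(n_samples = n_samples, n_splits = as.integer(n_splits),
                 fractions = as.numeric(fractions),
                 base_seed = as.integer(base_seed),
                 train_size = n_train, val_size = n_val, test_size = n_test,
                 splits = splits),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split plan: N = %d splits of %d samples into |T|=%d, |V|=%d, |E|=%d (seed %d)\n",
              x$n_splits, x$n_samples, x$train_size, x$val_size, x$test_size,
              x$base_seed))
  invisible(x)
}

#' Schedule of nested training-subset sizes
#'
#' Builds the K increasing training sizes `m_1 < ... < m_K = train_size` at
#' which learning-curve models are trained. Log spacing (the default)
#' samples sizes evenly on the log axis, matching how learning curves are
#' read on log-log plots; linear spacing and explicit user lists are also
#' supported. Sizes are rounded to integers and deduplicated; if rounding
#' collapses sizes the realized K is smaller than requested and a warning
#' reports it.
#'
#' @param train_size Full training-set size `|T|` (the last size).
#' @param K Requested number of subsets.
#' @param m_min Smallest size. Default `max(32, ceiling(train_size / 512))`.
#' @param spacing One of `"log"`, `"linear"`, `"explicit"`.
#' @param sizes Explicit increasing size vector (only with
#'   `spacing = "explicit"`; its last element must equal `train_size`).
#'
#' @return Object of class `"subset_schedule"`: list with `sizes`,
#'   `spacing`, `requested_k`, `realized_k`.
#' @examples
#' make_schedule(1000, K = 3, m_min = 10)$sizes  # 10, 100, 1000
#' @export
make_schedule <- function(train_size, K = 10, m_min = NULL,
                          spacing = c("log", "linear", "explicit"),
                          sizes = NULL) {
  spacing <- match.arg(spacing)
  stopifnot(length(train_size) == 1, train_size >= 1, K >= 1)
  if (spacing == "explicit") {
    if (is.null(sizes)) stop("explicit spacing requires 'sizes'")
    out <- as.integer(round(sizes))
    K <- length(out)
  } else {
    if (is.null(m_min)) m_min <- max(32, ceiling(train_size / 512))
    m_min <- min(m_min, train_size)
    stopifnot(m_min >= 1)
    raw <- if (K == 1) train_size
           else if (spacing == "log")
             exp(seq(log(m_min), log(train_size), length.out = K))
           else seq(m_min, train_size, length.out = K)
    out <- as.integer(round(raw))
  }
  out <- sort(unique(out))
  if (any(out < 1)) stop("all subset sizes must be >= 1")
  if (out[length(out)] != train_size)
    stop("the largest subset size must equal train_size")
  if (length(out) < K)
    warning(sprintf("rounding collapsed the schedule: realized K = %d < requested K = %d",
                    length(out), K))
  structure(list(sizes = out, spacing = spacing,
                 requested_k = as.integer(K), realized_k = length(out)),
            class = "subset_schedule")
}

#' @export
print.subset_schedule <- function(x, ...) {
  cat(sprintf("subset schedule (%s): K = %d sizes in [%d, %d]\n",
              x$spacing, x$realized_k, min(x$sizes), max(x$sizes)))
  invisible(x)
}

#' Extract the k-th nested training subset of a split
#'
#' Returns the first `m_k` indices of the shuffled training list of split
#' `split_index`, so each subset contains all samples of the preceding one
#' by construction, and the K-th subset is the full training set. All K
#' subsets of a split share that split's validation and test sets.
#'
#' @param plan A [make_splits()] plan.
#' @param split_index Split number in `1:plan$n_splits`.
#' @param schedule A [make_schedule()] schedule with
#'   `max(sizes) == plan$train_size`.
#' @param k Subset number in `1:schedule$realized_k`.
#'
#' @return Integer vector of `m_k` training sample indices.
#' @export
nested_subset <- function(plan, split_index, schedule, k) {
  stopifnot(inherits(plan, "split_plan"), inherits(schedule, "subset_schedule"))
  if (split_index < 1 || split_index > plan$n_splits) stop("split_index out of range")
  if (k < 1 || k > schedule$realized_k) stop("subset index k out of range")
  m_k <- schedule$sizes[k]
  if (max(schedule$sizes) > plan$train_size)
    stop("schedule exceeds the plan's training size")
  plan$splits[[split_index]]$train[seq_len(m_k)]
}

#' Enumerate all (split, subset) training tasks of a run
#'
#' A dry-run accounting of the workload: one model is trained per
#' (split, subset) pair, so a plan with N splits and a schedule with K
#' sizes yields N x K tasks.
#'
#' @inheritParams nested_subset
#' @return Data frame with columns `split`, `subset`, `train_size`; one row
#'   per training task.
#' @examples
#' plan <- make_splits(1000, n_splits = 4, base_seed = 1)
#' sched <- make_schedule(plan$train_size, K = 5)
#' nrow(lc_tasks(plan, sched))  # 20
#' @export
lc_tasks <- function(plan, schedule) {
  stopifnot(inherits(plan, "split_plan"), inherits(schedule, "subset_schedule"))
  expand.grid(subset = seq_len(schedule$realized_k),
              split = seq_len(plan$n_splits))[, c("split", "subset")] |>
    transform(train_size = schedule$sizes[subset])
}
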