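# Global sensitivity of the experiment outcomes to the core parameters:
# log-uniform hypercube sampling, boolean outcome matrix, binned
# success-rate statistic with a permutation null.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Sample core parameter sets around the defaults
#'
#' Each of the 30 core constants is drawn independently, uniformly on the
#' log scale, over `factor_range` times its default (default one half to
#' double).  `RSK1_total` is not sampled: it is an experiment-level pool
#' size, not a kinetic constant.
#'
#' @param defaults Parameter vector from [default_parameters()].
#' @param n Number of parameter sets.
#' @param seed Integer seed; the draw is reproducible given `seed`.
#' @param factor_range Length-2 multiplier range, default `c(0.5, 2)`.
#' @return List of class `"pias3net_sample"`: `matrix` (`n` x 30, columns
#'   named by parameter), `defaults`, `seed`, `factor_range`.
#' @export
sample_parameters <- function(defaults = default_parameters(), n,
                              seed = 0, factor_range = c(0.5, 2)) {
  stopifnot(n >= 1, length(factor_range) == 2,
            factor_range[1] > 0, factor_range[2] >= factor_range[1])
  nm <- core_parameter_names()
  base <- as.numeric(defaults[nm])
  if (any(base <= 0)) {
    stop("log-uniform sampling requires positive defaults", call. = FALSE)
  }
  m <- with_seed(seed, {
    u <- matrix(stats::runif(n * length(nm),
                             log(factor_range[1]), log(factor_range[2])),
                nrow = n)
    sweep(exp(u), 2, base, `*`)
  })
  colnames(m) <- nm
  structure(list(matrix = m, defaults = defaults, seed = seed,
                 factor_range = factor_range),
            class = "pias3net_sample")
}

#' Outcome matrix of the experiment catalog over a parameter sample
#'
#' Runs the full catalog once per sampled parameter set, keeping every
#' experiment-specific setting (transfection levels, activation steps,
#' mutant edits) fixed; only the 30 core constants vary.  Solver failures
#' are recorded as `NA` and excluded from success rates.
#'
#' @param sample A `"pias3net_sample"`.
#' @param catalog Experiment catalog.
#' @param atol,rtol Integration tolerances used for the scan.
#' @param progress Print a dot every 100 rows.
#' @return List of class `"pias3net_outcomes"`: `outcomes` (`n` x 28
#'   logical matrix, columns named by experiment id), `success_rate`
#'   (per-experiment column mean over non-missing rows), `n_error`.
#' @export
outcome_matrix <- function(sample, catalog = experiment_catalog(),
                           atol = 1e-8, rtol = 1e-6, progress = FALSE) {
  n <- nrow(sample$matrix)
  ids <- vapply(catalog, function(s) as.character(s$id), "")
  out <- matrix(NA, nrow = n, ncol = length(catalog),
                dimnames = list(NULL, ids))
  base <- sample$defaults
  for (r in seq_len(n)) {
    p <- base
    p[colnames(sample$matrix)] <- sample$matrix[r, ]
    batch <- run_all_experiments(p, catalog = catalog,
                                 atol = atol, rtol = rtol)
    out[r, names(batch$passes)] <- batch$passes
    if (progress && r %% 100 == 0) cat(".")
  }
  if (progress) cat("\n")
  structure(list(outcomes = out,
                 success_rate = colMeans(out, na.rm = TRUE),
                 n_error = sum(is.na(out))),
            class = "pias3net_outcomes")
}

#' Binned success-rate sensitivity statistic
#'
#' Sorts the parameter sets by one parameter, splits them into
#' `n_bins` equal rank-bins, and sums the absolute deviations of the
#' per-bin success rate from the overall success rate:
#' `s = sum_k |f^k - f|`.  The statistic is rank-based, hence invariant
#' under strictly monotone transforms of the parameter, non-negative,
#' and bounded by `n_bins * max(f, 1 - f)`.
#'
#' @param param_values Numeric vector (one parameter, `n` samples).
#' @param outcomes Logical vector of per-sample successes (`NA` allowed,
#'   excluded from rates).
#' @param n_bins Number of rank-bins; `n` must be divisible by it.
#' @return The sensitivity statistic (scalar).
#' @export
sensitivity_measure <- function(param_values, outcomes, n_bins = 100) {
  n <- length(param_values)
  stopifnot(length(outcomes) == n)
  if (n %% n_bins != 0) {
    stop("sample size must be divisible by the number of bins", call. = FALSE)
  }
  ord <- order(param_values)           # ties broken by original index (stable)
  f <- mean(outcomes, na.rm = TRUE)
  bin <- rep(seq_len(n_bins), each = n %/% n_bins)
  fk <- tapply(as.numeric(outcomes[ord]), bin, mean, na.rm = TRUE)
  sum(abs(fk - f), na.rm = TRUE)
}

# bin rates for all experiments at once given a row ordering
bin_rates <- function(outcomes_num, ord, n_bins) {
  n <- nrow(outcomes_num)
  bin <- rep(seq_len(n_bins), each = n %/% n_bins)
  cnt <- rowsum((!is.na(outcomes_num[ord, , drop = FALSE])) * 1, bin)
  sums <- rowsum(outcomes_num[ord, , drop = FALSE], bin, na.rm = TRUE)
  sums / cnt
}

#' Full sensitivity analysis with permutation filtering
#'
#' Computes the `n_experiments` x 30 matrix of binned success-rate
#' sensitivities, a permutation null (the maximum statistic over
#' `n_permutations` random orderings of the parameter values), the
#' filtered matrix with sub-threshold entries zeroed, and the row-wise
#' normalization.  One seeded permutation stream is shared across
#' parameters: a permuted ordering is outcome-side only, so the null is
#' identical for every parameter and reusing the draws reduces
#' Monte-Carlo variance.
#'
#' @param sample A `"pias3net_sample"`.
#' @param outcomes A `"pias3net_outcomes"` (or a logical matrix).
#' @param n_bins Number of rank-bins (default 100).
#' @param n_permutations Permutations for the null (default 1000).
#' @param seed Seed for the permutation stream.
#' @return List of class `"pias3net_sensitivity"`: `s` (raw statistic
#'   matrix, experiments x parameters), `threshold` (same shape),
#'   `filtered`, `normalized` (rows scaled to max 1; all-zero rows left
#'   at zero), `success_rate`, `n_bins`, `n_permutations`, `seed`.
#' @export
sensitivity_analysis <- function(sample, outcomes, n_bins = 100,
                                 n_permutations = 1000, seed = 0) {
  om <- if (inherits(outcomes, "pias3net_outcomes")) outcomes$outcomes else outcomes
  n <- nrow(om)
  stopifnot(n == nrow(sample$matrix), n_permutations >= 1)
  if (n %% n_bins != 0) {
    stop("sample size must be divisible by the number of bins", call. = FALSE)
  }
  onum <- om * 1.0
  f <- colMeans(onum, na.rm = TRUE)
  ids <- colnames(om)
  pn <- colnames(sample$matrix)

  s <- matrix(0, nrow = ncol(om), ncol = ncol(sample$matrix),
              dimnames = list(ids, pn))
  for (j in seq_along(pn)) {
    ord <- order(sample$matrix[, j])
    fk <- bin_rates(onum, ord, n_bins)
    s[, j] <- colSums(abs(sweep(fk, 2, f)), na.rm = TRUE)
  }

  # permutation null: max statistic over random orderings, shared across
  # parameters (a permuted parameter column induces a uniformly random
  # ordering of the outcome rows regardless of the column's values)
  null_max <- rep(0, ncol(om))
  with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      ord <- sample.int(n)
      fk <- bin_rates(onum, ord, n_bins)
      sp <- colSums(abs(sweep(fk, 2, f)), na.rm = TRUE)
      null_max <- pmax(null_max, sp)
    }
  })
  threshold <- matrix(null_max, nrow = ncol(om), ncol = ncol(sample$matrix),
                      dimnames = dimnames(s))
  filtered <- ifelse(s > threshold, s, 0)
  structure(list(s = s, threshold = threshold, filtered = filtered,
                 normalized = normalize_sensitivity(filtered),
                 success_rate = f, n_bins = n_bins,
                 n_permutations = n_permutations, seed = seed),
            class = "pias3net_sensitivity")
}

#' Row-normalize a sensitivity matrix
#'
#' Divides each experiment's row by its maximum entry, mapping values to
#' `[0, 1]`; all-zero rows are left as zeros.
#'
#' @param s Sensitivity matrix (experiments x parameters).
#' @return Matrix of the same shape.
#' @export
normalize_sensitivity <- function(s) {
  mx <- apply(s, 1, max)
  out <- s / ifelse(mx > 0, mx, 1)
  dimnames(out) <- dimnames(s)
  out
}

#' Parameters with no detected effect on any experiment
#'
#' @param sens A `"pias3net_sensitivity"` or a filtered sensitivity
#'   matrix.
#' @return Character vector of parameter names whose filtered
#'   sensitivity is zero for every experiment.
#' @export
insensitive_parameters <- function(sens) {
  m <- if (inherits(sens, "pias3net_sensitivity")) sens$filtered else sens
  colnames(m)[colSums(m != 0) == 0]
}
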