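#' Root-mean-square error
#'
#' @param y Ground-truth values.
#' @param yhat Predictions, same length.
#' @return `sqrt(mean((yhat - y)^2))`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat have different lengths")
  if (length(y) == 0L) stop("empty input")
  sqrt(mean((yhat - y)^2))
}

#' Normalised root-mean-square error
#'
#' RMSE divided by the range of the ground-truth values,
#' `NRMSE = RMSE / (max(y) - min(y))`. A constant ground truth has zero
#' range and is an error.
#'
#' @param y Ground-truth values (length >= 2, non-constant).
#' @param yhat Predictions.
#' @return Scalar NRMSE.
#' @export
nrmse <- function(y, yhat) {
  if (length(y) < 2L) stop("need at least two samples")
  rng <- max(y) - min(y)
  if (rng == 0) stop("ground truth is constant: NRMSE undefined (zero range)")
  rmse(y, yhat) / rng
}

#' Coefficient of repeatability
#'
#' `CR = 1.96 * sqrt(mean((yhat - y)^2))`; under approximate normality 95%
#' of prediction-truth differences are expected inside `[-CR, CR]`.
#'
#' @param y Ground-truth values (length >= 1).
#' @param yhat Predictions.
#' @return Scalar CR (`= 1.96 * RMSE` identically).
#' @export
coefficient_of_repeatability <- function(y, yhat) {
  1.96 * rmse(y, yhat)
}

#' Bland-Altman points
#'
#' Returns one `(mean, difference)` pair per sample: the pair mean
#' `(yhat + y) / 2` against the difference `yhat - y`, the conventional
#' agreement plot between a prediction and its reference.
#'
#' @param y Ground-truth values.
#' @param yhat Predictions.
#' @return Data frame with columns `mean` and `difference`.
#' @export
bland_altman <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat have different lengths")
  data.frame(mean = (yhat + y) / 2, difference = yhat - y)
}

#' Evaluate predictions against a reference
#'
#' @param y Ground truth.
#' @param yhat Predictions.
#' @param parameter,model Optional provenance labels.
#' @return An `eval_result` list: `nrmse`, `rmse`, `cr`,
#'   `bland_altman_points`, `n`, `parameter`, `model`.
#' @export
evaluate_predictions <- function(y, yhat, parameter = NA_character_,
                                 model = NA_character_) {
  structure(list(nrmse = nrmse(y, yhat), rmse = rmse(y, yhat),
                 cr = coefficient_of_repeatability(y, yhat),
                 bland_altman_points = bland_altman(y, yhat),
                 n = length(y), parameter = parameter, model = model),
            class = "eval_result")
}

#' Split cases into training and test sets
#'
#' Case-level (patient-level) split so no case contributes voxels to both
#' sides; the conventional split is four fifths for training.
#'
#' @param case_ids Vector of case identifiers (>= 2).
#' @param train_fraction Fraction of cases assigned to training
#'   (default 0.8).
#' @param seed Integer seed.
#' @return List with `train` and `test` id vectors: disjoint, exhaustive,
#'   both non-empty.
#' @export
split_cases <- function(case_ids, train_fraction = 0.8, seed = 1L) {
  n <- length(case_ids)
  if (n < 2L) stop("need at least two cases to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must lie in (0, 1)")
  n_train <- round(train_fraction * n)
  if (n_train < 1L || n_train > n - 1L)
    stop("`train_fraction` leaves one side of the split empty")
  idx <- with_seed(seed, sample(n, n_train))
  list(train = case_ids[sort(idx)], test = case_ids[sort(setdiff(seq_len(n), idx))])
}

#' Training-set-size sweep
#'
#' Trains each regression family on growing prefixes of a fixed, shuffled
#' training pool and scores NRMSE and CR on a fixed test set; training sets
#' are nested (the first `n` rows of the pool), so differences across sizes
#' reflect sample count only.
#'
#' @param train_data A `feature_dataset` used as the training pool.
#' @param test_data A `feature_dataset` from held-out cases.
#' @param families Regression family names (default all six).
#' @param sizes Training sizes, ascending; default a geometric grid of 8
#'   points from 100 to 16,000 (capped at the pool size).
#' @param seed Integer seed (pool shuffle + model seeds).
#' @param ... Extra arguments forwarded to [fit_regressor()].
#' @return Data frame: `family`, `n_train`, `nrmse`, `cr`, `parameter`,
#'   `e`, `seed`.
#' @export
sample_size_experiment <- function(train_data, test_data,
                                   families = regressor_families(),
                                   sizes = NULL, seed = 1L, ...) {
  stopifnot(inherits(train_data, "feature_dataset"),
            inherits(test_data, "feature_dataset"))
  pool_n <- nrow(train_data$X)
  if (is.null(sizes))
    sizes <- unique(round(exp(seq(log(100), log(16000), length.out = 8))))
  sizes <- sizes[sizes <= pool_n]
  if (length(sizes) == 0L || is.unsorted(sizes))
    stop("`sizes` must be ascending and within the pool size")
  ord <- with_seed(seed, sample(pool_n))
  rows <- list()
  for (fam in families) {
    for (n in sizes) {
      take <- ord[seq_len(n)]
      m <- fit_regressor(fam, train_data$X[take, , drop = FALSE],
                         train_data$y[take], seed = seed, ...)
      yhat <- predict(m, test_data$X)
      rows[[length(rows) + 1L]] <-
        data.frame(family = fam, n_train = n,
                   nrmse = nrmse(test_data$y, yhat),
                   cr = coefficient_of_repeatability(test_data$y, yhat),
                   parameter = train_data$provenance$parameter,
                   e = train_data$provenance$e, seed = seed)
      rm(m); gc(FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Patch-size sweep
#'
#' Rebuilds the regression dataset for each patch half-width `e` (window
#' `2e+1`) at a fixed sample budget and scores each family on the fixed test
#' cases.
#'
#' @param train_cases,test_cases Lists of cases as accepted by
#'   [build_dataset()].
#' @param parameter Target perfusion parameter.
#' @param families Regression family names.
#' @param e_values Patch half-widths (default `0:8`, windows 1x1 to 17x17).
#' @param n_samples Training rows per dataset (default 15,000).
#' @param n_test Test rows drawn from the test cases.
#' @param seed Integer seed.
#' @param ... Extra arguments forwarded to [fit_regressor()].
#' @return Data frame: `family`, `e`, `window`, `feature_width`, `nrmse`,
#'   `cr`, `parameter`, `seed`.
#' @export
patch_size_experiment <- function(train_cases, test_cases, parameter,
                                  families = regressor_families(),
                                  e_values = 0:8, n_samples = 15000L,
                                  n_test = 2000L, seed = 1L, ...) {
  rows <- list()
  for (e in e_values) {
    tr <- build_dataset(train_cases, parameter, e = e,
                        n_samples = n_samples, seed = seed)
    te <- build_dataset(test_cases, parameter, e = e, n_samples = n_test,
                        seed = seed + 1000L)
    for (fam in families) {
      m <- fit_regressor(fam, tr$X, tr$y, seed = seed, ...)
      yhat <- predict(m, te$X)
      rows[[length(rows) + 1L]] <-
        data.frame(family = fam, e = e, window = 2L * e + 1L,
                   feature_width = ncol(tr$X),
                   nrmse = nrmse(te$y, yhat),
                   cr = coefficient_of_repeatability(te$y, yhat),
                   parameter = parameter, seed = seed)
    }
  }
  do.call(rbind, rows)
}

#' Paired-bootstrap comparison of NRMSE between two prediction sets
#'
#' Resamples cases (rows) with replacement and reports the bootstrap
#' distribution of the NRMSE difference `nrmse(a) - nrmse(b)`; a two-sided
#' p-value is estimated from the fraction of resamples crossing zero.
#'
#' @param y Ground truth.
#' @param yhat_a,yhat_b Two prediction vectors for the same samples.
#' @param n_boot Number of resamples (default 10,000).
#' @param seed Integer seed.
#' @return List: `delta` (observed difference), `ci` (2.5/97.5 percentiles),
#'   `p_value`.
#' @export
bootstrap_nrmse_difference <- function(y, yhat_a, yhat_b, n_boot = 10000L,
                                       seed = 1L) {
  n <- length(y)
  obs <- nrmse(y, yhat_a) - nrmse(y, yhat_b)
  deltas <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample(n, n, replace = TRUE)
      if (max(y[idx]) == min(y[idx])) return(NA_real_)
      nrmse(y[idx], yhat_a[idx]) - nrmse(y[idx], yhat_b[idx])
    }, numeric(1))
  })
  deltas <- deltas[is.finite(deltas)]
  p <- 2 * min(mean(deltas >= 0), mean(deltas <= 0))
  list(delta = obs,
       ci = stats::quantile(deltas, c(0.025, 0.975), names = FALSE),
       p_value = min(1, p))
}
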