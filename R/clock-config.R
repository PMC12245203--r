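#' Configure the Muscle Age clock fit
#'
#' Settings for the permutation-averaged elastic-net procedure: number of
#' resampled train/test permutations, held-out fraction, cross-validation
#' folds, hyperparameter grids, the retention threshold for parsimonious
#' refitting and the percentile bounds of the ager trichotomy.
#'
#' `alpha` here is the overall regularisation strength and `l1_ratio` the
#' L1/L2 mixing weight (the elastic-net convention the model was described
#' in); they map onto `glmnet`'s `lambda` and `alpha` respectively. With
#' `alpha_grid = NULL` each fit uses a 100-point log-spaced path auto-scaled
#' from the training data.
#'
#' @param n_permutations Number of train/test permutations (default 100).
#' @param test_fraction Held-out fraction per permutation (default 0.2).
#' @param cv_folds Cross-validation folds for hyperparameter selection.
#' @param alpha_grid Positive regularisation strengths, or `NULL` for an
#'   auto-scaled path.
#' @param l1_ratio_grid Mixing weights in (0, 1].
#' @param selection_threshold Minimum permutation-mean standardized
#'   coefficient magnitude (years per feature SD) a feature must reach to be
#'   retained in the parsimonious model (default 1).
#' @param selection_rule `"mean_magnitude"` (default) retains features with
#'   `|mean coefficient| >= threshold`; `"coefficient_sd"` retains features
#'   whose mean magnitude exceeds `threshold` times the SD of their
#'   coefficient across permutations (an alternative reading of a
#'   "1 standard deviation" rule).
#' @param percentile_bounds Lower/upper percentile of the trichotomy
#'   (default `c(25, 75)`).
#' @param standardize_per_split Re-standardize predictors within each
#'   training split instead of freezing full-sample parameters.
#' @param pooled_residualization Residualize predicted on chronological age
#'   across sexes pooled rather than within each sex.
#' @param base_seed Base seed; permutation `k` uses `base_seed + k`.
#' @return An object of class `clock_config`.
#' @export
clock_config <- function(n_permutations = 100,
                         test_fraction = 0.2,
                         cv_folds = 5,
                         alpha_grid = NULL,
                         l1_ratio_grid = c(0.1, 0.5, 0.7, 0.9, 0.95, 1.0),
                         selection_threshold = 1.0,
                         selection_rule = c("mean_magnitude", "coefficient_sd"),
                         percentile_bounds = c(25, 75),
                         standardize_per_split = FALSE,
                         pooled_residualization = FALSE,
                         base_seed = 1L) {
  selection_rule <- match.arg(selection_rule)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (cv_folds < 2) stop("`cv_folds` must be at least 2", call. = FALSE)
  if (!is.null(alpha_grid)) {
    if (!length(alpha_grid) || any(alpha_grid <= 0)) {
      stop("`alpha_grid` must be a non-empty set of positive values", call. = FALSE)
    }
  }
  if (!length(l1_ratio_grid) || any(l1_ratio_grid <= 0 | l1_ratio_grid > 1)) {
    stop("`l1_ratio_grid` must be a non-empty set of values in (0, 1]", call. = FALSE)
  }
  pb <- percentile_bounds
  if (length(pb) != 2 || pb[1] < 0 || pb[1] >= pb[2] || pb[2] > 100) {
    stop("`percentile_bounds` must satisfy 0 <= lo < hi <= 100", call. = FALSE)
  }
  if (n_permutations < 1) stop("`n_permutations` must be >= 1", call. = FALSE)
  structure(
    list(n_permutations = as.integer(n_permutations),
         test_fraction = test_fraction,
         cv_folds = as.integer(cv_folds),
         alpha_grid = alpha_grid,
         l1_ratio_grid = l1_ratio_grid,
         selection_threshold = selection_threshold,
         selection_rule = selection_rule,
         percentile_bounds = pb,
         standardize_per_split = standardize_per_split,
         pooled_residualization = pooled_residualization,
         base_seed = as.integer(base_seed)),
    class = "clock_config")
}
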