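#' Residual age acceleration
#'
#' Regresses predicted age on chronological age by ordinary least squares and
#' returns the residuals, in years. This removes the inherent correlation of
#' the predicted age with chronological age, so positive values mean the
#' participant's predicted age is higher than expected for their
#' chronological age (accelerated ageing). By the OLS normal equations the
#' residuals have mean zero and zero correlation with chronological age.
#'
#' Used for both Muscle Age Acceleration (MAA) and Phenotypic Age
#' Acceleration (PhenoAA).
#'
#' @param predicted Predicted ages (years).
#' @param chronological Chronological ages (years), not constant.
#' @return Numeric vector of residuals (years).
#' @export
compute_age_acceleration <- function(predicted, chronological) {
  if (length(predicted) != length(chronological)) {
    stop("`predicted` and `chronological` must have equal length", call. = FALSE)
  }
  if (length(predicted) < 3) {
    stop("need at least 3 observations to residualize", call. = FALSE)
  }
  if (any(!is.finite(predicted)) || any(!is.finite(chronological))) {
    stop("non-finite values in ages", call. = FALSE)
  }
  if (sd(chronological) == 0) {
    stop("chronological age is constant; residualization is undefined",
         call. = FALSE)
  }
  as.numeric(resid(lm(predicted ~ chronological)))
}

#' Trichotomize age-acceleration scores into ager classes
#'
#' Rank-based partition: with `n` values and bounds `(lo, hi)` percentiles,
#' the `floor(lo/100 * n)` lowest-ranked values are `decelerated`, the
#' `floor((100 - hi)/100 * n)` highest-ranked are `accelerated`, and the rest
#' `normal`. Ties are broken by stable input order. At the default 25/75
#' bounds this reproduces exact quartile counts such as 53/109/53 for n = 215
#' and 33/67/33 for n = 133. Cutoffs are reported as the boundary order
#' statistics: the largest decelerated and the smallest accelerated value.
#'
#' @param maa Numeric vector of age-acceleration scores (years), `n >= 4`.
#' @param bounds Percentile pair `(lo, hi)` with `0 < lo < hi < 100`.
#' @return List with `class` (factor: decelerated/normal/accelerated, input
#'   order), `cutoffs` (named numeric `lower`, `upper`) and `counts`.
#' @export
classify_maa <- function(maa, bounds = c(25, 75)) {
  n <- length(maa)
  if (n < 4) stop("need at least 4 values to trichotomize", call. = FALSE)
  if (length(bounds) != 2 || bounds[1] <= 0 || bounds[1] >= bounds[2] ||
      bounds[2] >= 100) {
    stop("`bounds` must satisfy 0 < lo < hi < 100", call. = FALSE)
  }
  if (any(!is.finite(maa))) stop("non-finite age-acceleration values", call. = FALSE)
  k <- floor(bounds[1] / 100 * n)
  m <- floor((100 - bounds[2]) / 100 * n)
  ord <- order(maa)  # stable: ties keep input order
  lv <- c("decelerated", "normal", "accelerated")
  cls <- rep("normal", n)
  if (k > 0) cls[ord[seq_len(k)]] <- "decelerated"
  if (m > 0) cls[ord[seq.int(n - m + 1, n)]] <- "accelerated"
  sorted <- maa[ord]
  cutoffs <- c(lower = if (k > 0) sorted[k] else NA_real_,
               upper = if (m > 0) sorted[n - m + 1] else NA_real_)
  cls <- factor(cls, levels = lv)
  list(class = cls, cutoffs = cutoffs,
       counts = stats::setNames(as.integer(table(cls)), lv))
}
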