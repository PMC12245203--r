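#' Standardize feature columns
#'
#' Centers and scales the given columns to mean 0, SD 1, using the population
#' (1/n) SD convention, and returns the standardization parameters so the
#' transform can be reapplied exactly to new rows (frozen standardization).
#'
#' @param cohort A data.frame containing the features.
#' @param features Character vector of column names.
#' @return A list with `x` (numeric matrix, one standardized column per
#'   feature) and `params` (data.frame `feature`, `mean`, `sd`).
#' @export
standardize_features <- function(cohort, features) {
  missing <- setdiff(features, names(cohort))
  if (length(missing)) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(cohort[, features, drop = FALSE])
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("features contain non-finite values", call. = FALSE)
  n <- nrow(x)
  mu <- colMeans(x)
  sigma <- sqrt(colMeans(sweep(x, 2, mu)^2))
  zero <- sigma <= 0
  if (any(zero)) {
    stop("zero-variance feature(s): ", paste(features[zero], collapse = ", "),
         call. = FALSE)
  }
  params <- data.frame(feature = features, mean = unname(mu), sd = unname(sigma))
  list(x = sweep(sweep(x, 2, mu), 2, sigma, "/"), params = params)
}

#' Apply frozen standardization parameters to new rows
#'
#' @param cohort A data.frame containing the features named in `params`.
#' @param params The `params` element returned by [standardize_features()].
#' @return Numeric matrix of standardized columns.
#' @export
apply_standardization <- function(cohort, params) {
  missing <- setdiff(params$feature, names(cohort))
  if (length(missing)) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(cohort[, params$feature, drop = FALSE])
  storage.mode(x) <- "double"
  sweep(sweep(x, 2, params$mean), 2, params$sd, "/")
}
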