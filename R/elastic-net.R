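#' Elastic-net coefficients at a fixed penalty
#'
#' Low-level single fit of the elastic net at overall strength `alpha` and
#' mixing weight `l1_ratio` (so the penalty is
#' `alpha * (l1_ratio * ||b||_1 + (1 - l1_ratio)/2 * ||b||_2^2)` on the
#' mean-squared-error objective). As `alpha -> 0` the solution converges to
#' ordinary least squares. Predictors are used as supplied (no internal
#' standardization).
#'
#' @param x Numeric predictor matrix.
#' @param y Numeric response vector.
#' @param alpha Positive overall regularisation strength.
#' @param l1_ratio Mixing weight in (0, 1].
#' @return List with `intercept` and named `coefficients`.
#' @export
elastic_net_coefficients <- function(x, y, alpha, l1_ratio) {
  fit <- glmnet_fixed(x, y, l1_ratio, alpha)
  b <- coef(fit, s = alpha)
  list(intercept = as.numeric(b[1]),
       coefficients = stats::setNames(as.numeric(b[-1]), rownames(b)[-1]))
}

# glmnet fit guaranteed to contain `lambda` in its path (glmnet is unreliable
# when asked for a single lambda, so larger warm-start values are prepended).
glmnet_fixed <- function(x, y, l1_ratio, lambda) {
  path <- sort(unique(c(lambda * c(1000, 100, 10), lambda)), decreasing = TRUE)
  glmnet::glmnet(x, y, alpha = l1_ratio, lambda = path, standardize = FALSE)
}

# Mean cross-validated MSE at a fixed (l1_ratio, lambda) pair.
manual_cv_mse <- function(x, y, l1_ratio, lambda, foldid) {
  se <- numeric(0)
  for (f in sort(unique(foldid))) {
    tr <- foldid != f
    fit <- glmnet_fixed(x[tr, , drop = FALSE], y[tr], l1_ratio, lambda)
    pred <- predict(fit, x[!tr, , drop = FALSE], s = lambda)
    se <- c(se, (y[!tr] - as.numeric(pred))^2)
  }
  mean(se)
}

# Cross-validated selection of (l1_ratio, lambda) over the configured grids
# on one training set. Returns the chosen pair, its CV error and the glmnet
# fit on the full training data.
cv_select_enet <- function(x, y, config, foldid) {
  best <- list(cvm = Inf)
  user_grid <- config$alpha_grid
  for (l1 in config$l1_ratio_grid) {
    if (is.null(user_grid)) {
      cv <- glmnet::cv.glmnet(x, y, alpha = l1, foldid = foldid,
                              standardize = FALSE)
      i <- which.min(cv$cvm)
      cand <- list(lambda = cv$lambda[i], cvm = cv$cvm[i], fit = cv$glmnet.fit)
    } else if (length(user_grid) >= 2) {
      grid <- sort(unique(user_grid), decreasing = TRUE)
      cv <- glmnet::cv.glmnet(x, y, alpha = l1, lambda = grid,
                              foldid = foldid, standardize = FALSE)
      i <- which.min(cv$cvm)
      cand <- list(lambda = cv$lambda[i], cvm = cv$cvm[i], fit = cv$glmnet.fit)
    } else {
      lam <- user_grid[1]
      cvm <- manual_cv_mse(x, y, l1, lam, foldid)
      cand <- list(lambda = lam, cvm = cvm, fit = glmnet_fixed(x, y, l1, lam))
    }
    if (cand$cvm < best$cvm) {
      best <- cand
      best$l1_ratio <- l1
    }
  }
  best
}

#' Permutation-averaged elastic-net fit of age on standardized features
#'
#' The core resampling procedure of the clock: for each permutation `k`
#' (seeded with `base_seed + k`) the sample is split into train/test parts,
#' `(alpha, l1_ratio)` are selected on the training part by k-fold
#' cross-validated mean squared error over the configured grids, the model is
#' refitted on the training part at the selected pair, and the held-out RMSE,
#' R-squared and coefficients are recorded. Coefficients are averaged across
#' all permutations, zeros included, so shrinkage to zero carries selection
#' information into the mean.
#'
#' @param x Standardized predictor matrix (see [standardize_features()]).
#' @param age Chronological ages (years).
#' @param config A [clock_config()].
#' @return An object of class `fit_summary`: per-feature coefficient
#'   mean/SD, permutation-level records, and RMSE / R-squared mean and SD.
#' @export
fit_permuted_elastic_net <- function(x, age, config) {
  stopifnot(inherits(config, "clock_config"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x)
  if (length(age) != n) stop("`age` must match rows of `x`", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(age))) {
    stop("non-finite values in predictors or age", call. = FALSE)
  }
  n_test <- max(1L, round(config$test_fraction * n))
  n_train <- n - n_test
  if (n_train < 2 * config$cv_folds) {
    stop("sample too small: ", n_train, " training rows for ",
         config$cv_folds, "-fold cross-validation", call. = FALSE)
  }

  p <- ncol(x)
  coefs <- matrix(0, config$n_permutations, p,
                  dimnames = list(NULL, colnames(x)))
  intercepts <- rmse <- r2 <- numeric(config$n_permutations)
  records <- vector("list", config$n_permutations)

  for (k in seq_len(config$n_permutations)) {
    seed_k <- config$base_seed + k
    res <- with_local_seed(seed_k, {
      test_idx <- sort(sample(n, n_test))
      train_idx <- setdiff(seq_len(n), test_idx)
      foldid <- sample(rep(seq_len(config$cv_folds), length.out = n_train))

      xtr <- x[train_idx, , drop = FALSE]
      xte <- x[test_idx, , drop = FALSE]
      if (config$standardize_per_split) {
        mu <- colMeans(xtr)
        sigma <- sqrt(colMeans(sweep(xtr, 2, mu)^2))
        if (any(sigma <= 0)) stop("zero-variance feature in training split",
                                  call. = FALSE)
        xtr <- sweep(sweep(xtr, 2, mu), 2, sigma, "/")
        xte <- sweep(sweep(xte, 2, mu), 2, sigma, "/")
      }
      ytr <- age[train_idx]
      yte <- age[test_idx]

      sel <- cv_select_enet(xtr, ytr, config, foldid)
      b <- coef(sel$fit, s = sel$lambda)
      pred <- as.numeric(predict(sel$fit, xte, s = sel$lambda))
      ss_res <- sum((yte - pred)^2)
      ss_tot <- sum((yte - mean(yte))^2)
      list(coefs = as.numeric(b[-1]),
           intercept = as.numeric(b[1]),
           rmse = sqrt(mean((yte - pred)^2)),
           r2 = 1 - ss_res / ss_tot,
           record = data.frame(permutation = k, seed = seed_k,
                               split_hash = fnv1a_hash(test_idx),
                               alpha = sel$lambda, l1_ratio = sel$l1_ratio,
                               rmse = sqrt(mean((yte - pred)^2)),
                               r2 = 1 - ss_res / ss_tot))
    })
    coefs[k, ] <- res$coefs
    intercepts[k] <- res$intercept
    rmse[k] <- res$rmse
    r2[k] <- res$r2
    records[[k]] <- res$record
  }

  structure(
    list(features = colnames(x),
         coef_mean = colMeans(coefs),
         coef_sd = apply(coefs, 2, sd),
         coef_matrix = coefs,
         intercept_mean = mean(intercepts),
         rmse_mean = mean(rmse), rmse_sd = sd(rmse),
         r2_mean = mean(r2), r2_sd = sd(r2),
         records = do.call(rbind, records),
         n = n,
         config = config),
    class = "fit_summary")
}

#' @export
print.fit_summary <- function(x, ...) {
  cat("Permutation-averaged elastic-net fit\n")
  cat(sprintf("  %d permutations, n = %d, %d features\n",
              nrow(x$records), x$n, length(x$features)))
  cat(sprintf("  RMSE = %.2f +/- %.2f years, R^2 = %.2f +/- %.2f\n",
              x$rmse_mean, x$rmse_sd, x$r2_mean, x$r2_sd))
  ord <- order(abs(x$coef_mean), decreasing = TRUE)
  tab <- data.frame(feature = x$features[ord],
                    beta_mean = round(x$coef_mean[ord], 3),
                    beta_sd = round(x$coef_sd[ord], 3))
  rownames(tab) <- NULL
  print(tab)
  invisible(x)
}

#' Retain features for the parsimonious model
#'
#' Applies the retention rule to a permutation-averaged fit: by default a
#' feature is retained when its permutation-mean standardized coefficient is
#' at least `threshold` in magnitude, i.e. it shifts predicted Muscle Age by
#' at least `threshold` years per SD of the test result.
#'
#' @param summary A `fit_summary` from [fit_permuted_elastic_net()].
#' @param threshold Retention threshold (years per feature SD).
#' @param rule `"mean_magnitude"` (default) or `"coefficient_sd"`; see
#'   [clock_config()].
#' @return Character vector of retained features, ordered by descending mean
#'   coefficient magnitude.
#' @export
select_parsimonious <- function(summary, threshold = 1,
                                rule = c("mean_magnitude", "coefficient_sd")) {
  stopifnot(inherits(summary, "fit_summary"))
  rule <- match.arg(rule)
  mag <- abs(summary$coef_mean)
  keep <- if (rule == "mean_magnitude") {
    mag >= threshold
  } else {
    mag >= threshold * summary$coef_sd
  }
  if (!any(keep)) {
    stop("no feature passes the retention threshold (", threshold,
         "); consider lowering it", call. = FALSE)
  }
  names(sort(mag[keep], decreasing = TRUE))
}

#' Fit the parsimonious sex-specific Muscle Age model
#'
#' Reruns the permuted elastic-net procedure on the retained features only,
#' within one sex. The final model's coefficients are the permutation means;
#' its intercept is the mean age of the fitting sample (predictors are
#' standardized, so a participant at the feature means is predicted at the
#' sample mean age); standardization parameters are frozen from the full
#' sex-specific sample.
#'
#' @param cohort Cohort data.frame restricted to (or containing) one sex.
#' @param retained Non-empty character vector of feature names.
#' @param config A [clock_config()].
#' @param sex `"F"` or `"M"`; rows of other sexes are dropped.
#' @return List with `model` (class `muscle_age_model`) and `fit` (the
#'   phase-2 `fit_summary`).
#' @export
fit_final_model <- function(cohort, retained, config, sex) {
  if (!length(retained)) stop("`retained` must be non-empty", call. = FALSE)
  sub <- cohort[cohort$sex == sex, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for sex ", sex, call. = FALSE)
  std <- standardize_features(sub, retained)
  fit <- fit_permuted_elastic_net(std$x, sub$age, config)
  model <- structure(
    list(sex = sex,
         features = retained,
         coefficients = fit$coef_mean,
         intercept = mean(sub$age),
         standardization = std$params,
         base_seed = config$base_seed),
    class = "muscle_age_model")
  list(model = model, fit = fit)
}

#' @export
print.muscle_age_model <- function(x, ...) {
  cat(sprintf("Muscle Age model (sex %s): intercept %.2f years\n",
              x$sex, x$intercept))
  ord <- order(abs(x$coefficients), decreasing = TRUE)
  for (i in ord) {
    cat(sprintf("  %-20s beta = %+.2f years per SD\n",
                x$features[i], x$coefficients[i]))
  }
  invisible(x)
}

#' Predict Muscle Age for new participants
#'
#' Applies the frozen standardization and the model's averaged coefficients:
#' `intercept + sum(beta_i * (x_i - mu_i) / sigma_i)`.
#'
#' @param model A `muscle_age_model` from [fit_final_model()].
#' @param cohort Data.frame containing all retained feature columns.
#' @return Numeric vector of predicted Muscle Ages (years).
#' @export
predict_muscle_age <- function(model, cohort) {
  stopifnot(inherits(model, "muscle_age_model"))
  z <- apply_standardization(cohort, model$standardization)
  as.numeric(model$intercept + z %*% model$coefficients)
}
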