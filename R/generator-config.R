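#' Motor-test battery used as clock predictors
#'
#' The nine EWGSOP2-derived motor-functional and muscle-mass measures that
#' enter the Muscle Age model by default: handgrip strength (kg), five-times
#' sit-to-stand time (s), skeletal and appendicular muscle mass (kg), gait
#' speed (m/s), SPPB score (0-12), timed up-and-go (s), six-minute walk
#' distance (m) and calf circumference (cm).
#'
#' @return Character vector of column names.
#' @export
clock_features <- function() {
  c("handgrip", "five_tsts", "smm", "asmm", "gait_speed",
    "sppb", "tug", "six_mwt", "calf_circumference")
}

#' Default per-sex linear ageing models for the motor battery
#'
#' One row per feature and sex: value at age 50 (`intercept50`), linear drift
#' per year of age (`slope`), residual SD around the age trend (`sd`) and a
#' physical floor below which values are resampled. Tests that worsen with age
#' (TUG, 5-TSTS) have positive slopes; strength, mass and walking-capacity
#' measures decline. Anthropometrics (weight, height) are generated without an
#' age trend.
#'
#' @return A data.frame with columns `feature`, `sex`, `intercept50`, `slope`,
#'   `sd`, `floor`.
#' @export
default_ageing_models <- function() {
  f <- data.frame(
    feature = c("handgrip", "five_tsts", "smm", "asmm", "gait_speed",
                "sppb", "tug", "six_mwt", "calf_circumference",
                "weight", "height"),
    intercept50 = c(26, 6.2, 18.5, 16.0, 1.65, 12.2, 5.6, 590, 36.5, 59.1, 154.1),
    slope = c(-0.30, 0.06, -0.08, -0.07, -0.008, -0.02, 0.065, -4.0, -0.05, 0, 0),
    sd = c(4.0, 1.2, 2.0, 1.6, 0.15, 0.5, 0.8, 60, 2.5, 7.5, 7.3),
    floor = c(1, 2, 5, 3, 0.2, -3, 2, 50, 20, 35, 130)
  )
  m <- data.frame(
    feature = f$feature,
    intercept50 = c(42, 6.4, 31.5, 24.0, 1.63, 12.2, 5.2, 610, 37.5, 76.2, 170.0),
    slope = c(-0.35, 0.06, -0.13, -0.11, -0.007, -0.02, 0.055, -4.0, -0.04, 0, 0),
    sd = c(5.0, 1.2, 2.5, 2.0, 0.15, 0.5, 0.75, 65, 2.5, 10.0, 6.9),
    floor = f$floor
  )
  f$sex <- "F"
  m$sex <- "M"
  out <- rbind(f, m)
  rownames(out) <- NULL
  out[, c("feature", "sex", "intercept50", "slope", "sd", "floor")]
}

#' Default blood-panel marker distributions
#'
#' Marker means and SDs for the optional haemato-chemical panel, in the units
#' expected by [phenoage()]: albumin (g/dL), creatinine (mg/dL), glucose
#' (mg/dL), C-reactive protein (mg/dL), lymphocyte percentage, mean
#' corpuscular volume (fL), red-cell distribution width (%), alkaline
#' phosphatase (U/L) and white blood cells (10^3 cells/uL).
#'
#' @return A data.frame with columns `marker`, `sex`, `mean`, `sd`, `floor`.
#' @export
default_blood_models <- function() {
  mk <- c("albumin", "creatinine", "glucose", "crp", "lymphocyte_pct",
          "mcv", "rdw_pct", "alkaline_phosphatase", "wbc")
  f <- data.frame(marker = mk,
                  mean = c(4.25, 0.78, 92, 0.38, 35, 87, 13.8, 76, 5.5),
                  sd   = c(0.30, 0.12, 11, 0.22, 7.0, 6.0, 1.1, 20, 1.4),
                  floor = c(2.5, 0.3, 50, 0.02, 5, 60, 10, 20, 2))
  m <- data.frame(marker = mk,
                  mean = c(4.26, 1.00, 96, 0.38, 30, 87, 13.8, 78, 6.1),
                  sd   = c(0.30, 0.15, 12, 0.22, 7.0, 6.0, 1.1, 20, 1.5),
                  floor = f$floor)
  f$sex <- "F"
  m$sex <- "M"
  out <- rbind(f, m)
  rownames(out) <- NULL
  out[, c("marker", "sex", "mean", "sd", "floor")]
}

#' Configure the synthetic-cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. Each motor
#' feature follows `intercept50 + slope * (age - 50) + N(0, sd)`, truncated at
#' a physical floor by resampling. When `target_r2` is set, the age slopes of
#' all trending features are rescaled by a common per-sex factor so that the
#' best linear predictor of age from the feature battery explains exactly
#' that fraction of age variance (see [implied_age_r2()]); residual SDs stay
#' at their configured, cohort-realistic values.
#'
#' @param n_participants Number of rows to generate.
#' @param sex_ratio Fraction of female participants in `[0, 1]`.
#' @param age_range Two ages (years), lower < upper.
#' @param age_distribution `"uniform"` over `age_range` (default) or
#'   `"truncated_normal"` with `age_mean`/`age_sd` truncated to `age_range`.
#' @param age_mean,age_sd Location/scale for the truncated-normal option.
#' @param ageing_models Per-sex feature models; see [default_ageing_models()].
#' @param blood_panel Logical; generate the haemato-chemical panel?
#' @param blood_models Per-sex marker models; see [default_blood_models()].
#' @param class_shifts Optional named list of per-marker additive shifts,
#'   each a numeric vector `c(decelerated =, normal =, accelerated =)`,
#'   applied to the blood panel according to the latent ager class.
#' @param acceleration_sd SD (years) of a latent per-participant muscular age
#'   acceleration added to the effective age driving the motor tests; 0
#'   disables it. Latent ager classes are the 25/75 rank-rule trichotomy of
#'   this latent acceleration (random classes when it is disabled).
#' @param target_r2 Fraction of age variance explained by the generative
#'   signal, or `NULL` to keep `ageing_models` SDs as given.
#' @param seed Integer seed; identical config + seed gives identical cohorts.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 215,
                             sex_ratio = 118 / 215,
                             age_range = c(50, 90),
                             age_distribution = c("uniform", "truncated_normal"),
                             age_mean = 66.0,
                             age_sd = 7.3,
                             ageing_models = default_ageing_models(),
                             blood_panel = TRUE,
                             blood_models = default_blood_models(),
                             class_shifts = NULL,
                             acceleration_sd = 0,
                             target_r2 = 0.40,
                             seed = 1L) {
  age_distribution <- match.arg(age_distribution)
  if (!is.numeric(n_participants) || n_participants < 1) {
    stop("`n_participants` must be a positive count", call. = FALSE)
  }
  if (!is.numeric(sex_ratio) || sex_ratio < 0 || sex_ratio > 1) {
    stop("`sex_ratio` must lie in [0, 1]", call. = FALSE)
  }
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    stop("`age_range` must be two ages with lo < hi", call. = FALSE)
  }
  need <- c("feature", "sex", "intercept50", "slope", "sd", "floor")
  if (!all(need %in% names(ageing_models))) {
    stop("`ageing_models` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(ageing_models$sd <= 0)) {
    bad <- unique(ageing_models$feature[ageing_models$sd <= 0])
    stop("`ageing_models` residual sd must be > 0 (offending feature: ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  if (blood_panel && any(blood_models$sd <= 0)) {
    stop("`blood_models` sd must be > 0", call. = FALSE)
  }
  if (!is.null(target_r2) && (target_r2 <= 0 || target_r2 >= 1)) {
    stop("`target_r2` must lie in (0, 1) or be NULL", call. = FALSE)
  }
  if (acceleration_sd < 0) stop("`acceleration_sd` must be >= 0", call. = FALSE)

  cfg <- structure(
    list(n_participants = as.integer(n_participants),
         sex_ratio = sex_ratio,
         age_range = as.numeric(age_range),
         age_distribution = age_distribution,
         age_mean = age_mean, age_sd = age_sd,
         ageing_models = ageing_models,
         blood_panel = isTRUE(blood_panel),
         blood_models = blood_models,
         class_shifts = class_shifts,
         acceleration_sd = acceleration_sd,
         target_r2 = target_r2,
         signal_scale = 1,
         seed = as.integer(seed)),
    class = "generator_config")

  if (!is.null(target_r2)) cfg <- scale_signal_to_r2(cfg, target_r2)
  cfg
}

# Variance of the age distribution implied by the config.
age_variance <- function(config) {
  if (config$age_distribution == "uniform") {
    diff(config$age_range)^2 / 12
  } else {
    lo <- (config$age_range[1] - config$age_mean) / config$age_sd
    hi <- (config$age_range[2] - config$age_mean) / config$age_sd
    z <- pnorm(hi) - pnorm(lo)
    d <- (stats::dnorm(lo) - stats::dnorm(hi)) / z
    config$age_sd^2 * (1 + (lo * stats::dnorm(lo) - hi * stats::dnorm(hi)) / z - d^2)
  }
}

# Signal-to-noise ratio lambda_i = slope_i^2 Var(age) / sd_i^2 per feature,
# for one sex (rows of ageing_models restricted to that sex).
signal_lambda <- function(models, var_age) {
  models$slope^2 * var_age / models$sd^2
}

#' Population R-squared of age on the generated feature battery
#'
#' Closed form for the fraction of age variance explained by the best linear
#' predictor of age from the features, per sex: with
#' `lambda_i = slope_i^2 Var(age) / sd_i^2`, the R-squared is
#' `sum(lambda) / (1 + sum(lambda))` (features independent given age).
#'
#' @param config A [generator_config()].
#' @return Named numeric vector, one value per sex.
#' @export
implied_age_r2 <- function(config) {
  va <- age_variance(config)
  vapply(c(F = "F", M = "M"), function(s) {
    m <- config$ageing_models[config$ageing_models$sex == s, ]
    S <- sum(signal_lambda(m, va))
    S / (1 + S)
  }, numeric(1))
}

# Rescale the age slopes of all trending features by a common factor so the
# implied R^2 equals `r2` in each sex. Scaling slopes rather than residual
# SDs changes the signal-to-noise identically (lambda depends on slope/sd
# only) but keeps the marginal feature SDs near their configured,
# cohort-realistic values.
scale_signal_to_r2 <- function(config, r2) {
  va <- age_variance(config)
  for (s in c("F", "M")) {
    idx <- config$ageing_models$sex == s & config$ageing_models$slope != 0
    if (!any(idx)) next
    m <- config$ageing_models[idx, ]
    S <- sum(signal_lambda(m, va))
    target_S <- r2 / (1 - r2)
    f <- sqrt(target_S / S)
    config$ageing_models$slope[idx] <- config$ageing_models$slope[idx] * f
    config$signal_scale <- f
  }
  config
}

#' Population standardized contributions of each feature
#'
#' The coefficient each feature would receive, per SD of the feature, in the
#' population least-squares regression of age on the standardized feature
#' battery: `sign(slope) * sd_age * sqrt(lambda (1 + lambda)) / (1 + sum(lambda))`
#' years per SD. This is the generative analogue of the clock's standardized
#' beta weights and the quantity parameter-recovery tests compare against.
#'
#' @param config A [generator_config()].
#' @return A data.frame with columns `feature`, `sex`, `contribution`.
#' @export
standardized_contributions <- function(config) {
  va <- age_variance(config)
  out <- lapply(c("F", "M"), function(s) {
    m <- config$ageing_models[config$ageing_models$sex == s, ]
    lam <- signal_lambda(m, va)
    contrib <- sign(m$slope) * sqrt(va) * sqrt(lam * (1 + lam)) / (1 + sum(lam))
    data.frame(feature = m$feature, sex = s, contribution = contrib)
  })
  do.call(rbind, out)
}

#' Calibrate the generator to exact standardized contributions
#'
#' Rewrites a generator configuration so that only the named features carry an
#' age signal, with slopes solved (residual SDs kept at their configured
#' values) so the population standardized contributions equal `contributions`
#' exactly, in both sexes. Used to set up parameter-recovery experiments with
#' known ground truth.
#'
#' @param config A [generator_config()].
#' @param contributions Named numeric vector, e.g.
#'   `c(tug = 2, handgrip = -1.5)`, in years of predicted age per feature SD.
#' @return The modified `generator_config` (with `target_r2` cleared).
#' @export
set_signal_contributions <- function(config, contributions) {
  stopifnot(length(contributions) >= 1, !is.null(names(contributions)))
  feats <- names(contributions)
  if (!all(feats %in% config$ageing_models$feature)) {
    stop("unknown feature in `contributions`: ",
         paste(setdiff(feats, config$ageing_models$feature), collapse = ", "),
         call. = FALSE)
  }
  va <- age_variance(config)
  sd_age <- sqrt(va)
  cmag <- abs(contributions)
  if (any(cmag >= sd_age)) {
    stop("standardized contributions must be smaller in magnitude than the age SD",
         call. = FALSE)
  }
  # Solve for lambda_i with common total T = 1 + sum(lambda):
  #   g(lambda_i) = c_i * T / sd_age  where  g(l) = sqrt(l (1 + l)).
  ginv <- function(y) (-1 + sqrt(1 + 4 * y^2)) / 2
  gap <- function(total) 1 + sum(ginv(cmag * total / sd_age)) - total
  # gap(1) > 0 and gap is eventually negative when contributions are feasible.
  upper <- 2
  while (gap(upper) > 0 && upper < 1e8) upper <- upper * 2
  if (gap(upper) > 0) {
    stop("contributions are jointly infeasible for this age distribution",
         call. = FALSE)
  }
  total <- stats::uniroot(gap, c(1, upper), tol = 1e-12)$root
  lambda <- ginv(cmag * total / sd_age)

  am <- config$ageing_models
  am$slope <- 0
  for (i in seq_along(contributions)) {
    rows <- am$feature == feats[i]
    am$slope[rows] <- sign(contributions[i]) *
      sqrt(lambda[i] / va) * am$sd[rows]
  }
  config$ageing_models <- am
  config$target_r2 <- NULL
  config
}
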