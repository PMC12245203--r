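#' Build the Muscle Age clock end to end
#'
#' Orchestrates the full sex-stratified procedure: freeze full-sample
#' standardization, phase-1 permuted elastic-net fit on the whole feature
#' battery, retention of features whose permutation-mean standardized
#' coefficient magnitude meets the threshold, phase-2 refit on the retained
#' features (the parsimonious model), prediction of Muscle Age, residual
#' Muscle Age Acceleration (MAA) against chronological age, and percentile
#' trichotomization into decelerated / normal / accelerated agers. Models,
#' residualization and cutoffs are sex-specific by default; set
#' `pooled_residualization` in the config to residualize and classify the
#' sexes jointly.
#'
#' Rows with missing age or feature values are dropped with a logged count.
#'
#' @param cohort Cohort data.frame with columns `id`, `sex`, `age` and the
#'   feature columns.
#' @param config A [clock_config()].
#' @param features Feature battery to use (default [clock_features()]).
#' @return An object of class `muscle_clock`: per-sex list with elements
#'   `phase1` (fit_summary), `retained`, `model` (muscle_age_model), `phase2`
#'   (fit_summary), `maa` (data.frame id, age, predicted, maa, class) and
#'   `cutoffs`; plus `config`, `features` and `n_dropped`.
#' @export
build_clock <- function(cohort, config = clock_config(),
                        features = clock_features()) {
  stopifnot(inherits(config, "clock_config"))
  need <- c("id", "sex", "age", features)
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  complete <- stats::complete.cases(cohort[, c("age", features)])
  n_dropped <- sum(!complete)
  if (n_dropped) {
    message("dropping ", n_dropped, " row(s) with missing age or features")
  }
  cohort <- cohort[complete, , drop = FALSE]

  sexes <- intersect(c("F", "M"), unique(cohort$sex))
  if (!length(sexes)) stop("no rows with sex F or M", call. = FALSE)

  per_sex <- list()
  for (s in sexes) {
    sub <- cohort[cohort$sex == s, , drop = FALSE]
    n_train <- nrow(sub) - max(1L, round(config$test_fraction * nrow(sub)))
    if (n_train < 2 * config$cv_folds) {
      stop("sex stratum ", s, " too small (", nrow(sub), " rows) for the ",
           "configured split and folds", call. = FALSE)
    }
    std <- standardize_features(sub, features)
    phase1 <- fit_permuted_elastic_net(std$x, sub$age, config)
    retained <- select_parsimonious(phase1, config$selection_threshold,
                                    config$selection_rule)
    final <- fit_final_model(sub, retained, config, s)
    predicted <- predict_muscle_age(final$model, sub)
    per_sex[[s]] <- list(phase1 = phase1, retained = retained,
                         model = final$model, phase2 = final$fit,
                         id = sub$id, age = sub$age, predicted = predicted)
  }

  if (config$pooled_residualization) {
    all_pred <- unlist(lapply(per_sex, `[[`, "predicted"))
    all_age <- unlist(lapply(per_sex, `[[`, "age"))
    all_maa <- compute_age_acceleration(all_pred, all_age)
    cl <- classify_maa(all_maa, config$percentile_bounds)
    offsets <- cumsum(c(0, vapply(per_sex, function(z) length(z$age), 0L)))
    for (i in seq_along(per_sex)) {
      idx <- seq.int(offsets[i] + 1, offsets[i + 1])
      per_sex[[i]]$maa_values <- all_maa[idx]
      per_sex[[i]]$class <- cl$class[idx]
      per_sex[[i]]$cutoffs <- cl$cutoffs
    }
  } else {
    for (s in names(per_sex)) {
      maa <- compute_age_acceleration(per_sex[[s]]$predicted, per_sex[[s]]$age)
      cl <- classify_maa(maa, config$percentile_bounds)
      per_sex[[s]]$maa_values <- maa
      per_sex[[s]]$class <- cl$class
      per_sex[[s]]$cutoffs <- cl$cutoffs
    }
  }

  for (s in names(per_sex)) {
    z <- per_sex[[s]]
    per_sex[[s]]$maa <- data.frame(id = z$id, sex = s, age = z$age,
                                   predicted = z$predicted,
                                   maa = z$maa_values, class = z$class)
    per_sex[[s]]$id <- per_sex[[s]]$age <- per_sex[[s]]$predicted <- NULL
    per_sex[[s]]$maa_values <- per_sex[[s]]$class <- NULL
  }

  structure(list(sexes = per_sex, config = config, features = features,
                 n_dropped = n_dropped),
            class = "muscle_clock")
}

#' @export
print.muscle_clock <- function(x, ...) {
  cat("Muscle Age clock\n")
  for (s in names(x$sexes)) {
    z <- x$sexes[[s]]
    cat(sprintf("Sex %s (n = %d): retained %s\n", s, nrow(z$maa),
                paste(z$retained, collapse = ", ")))
    cat(sprintf("  phase 2: RMSE = %.2f +/- %.2f, R^2 = %.2f +/- %.2f\n",
                z$phase2$rmse_mean, z$phase2$rmse_sd,
                z$phase2$r2_mean, z$phase2$r2_sd))
    cat(sprintf("  MAA cutoffs: %.2f / %.2f years; classes %s\n",
                z$cutoffs["lower"], z$cutoffs["upper"],
                paste(table(z$maa$class), collapse = "/")))
  }
  invisible(x)
}

#' Combined MAA table across sexes
#'
#' @param clock A `muscle_clock` from [build_clock()].
#' @return Data.frame with one row per participant: `id`, `sex`, `age`,
#'   `predicted`, `maa`, `class`.
#' @export
maa_table <- function(clock) {
  stopifnot(inherits(clock, "muscle_clock"))
  out <- do.call(rbind, lapply(clock$sexes, `[[`, "maa"))
  rownames(out) <- NULL
  out
}

#' Machine-readable run report for a fitted clock
#'
#' Serializable summary of an end-to-end clock build: per sex, the phase-1
#' and phase-2 coefficient summaries and fit metrics, the retained features,
#' the final model (coefficients, intercept, frozen standardization) and the
#' MAA table with cutoffs.
#'
#' @param clock A `muscle_clock` from [build_clock()].
#' @return A nested list suitable for [jsonlite::write_json()].
#' @export
clock_report <- function(clock) {
  stopifnot(inherits(clock, "muscle_clock"))
  fit_block <- function(fit) {
    list(coef_mean = as.list(fit$coef_mean),
         coef_sd = as.list(fit$coef_sd),
         rmse = c(mean = fit$rmse_mean, sd = fit$rmse_sd),
         r2 = c(mean = fit$r2_mean, sd = fit$r2_sd),
         records = fit$records)
  }
  sexes <- lapply(clock$sexes, function(z) {
    list(phase1 = fit_block(z$phase1),
         retained = z$retained,
         phase2 = fit_block(z$phase2),
         model = list(sex = z$model$sex,
                      features = z$model$features,
                      coefficients = as.list(z$model$coefficients),
                      intercept = z$model$intercept,
                      standardization = z$model$standardization,
                      base_seed = z$model$base_seed),
         cutoffs = as.list(z$cutoffs),
         maa = z$maa)
  })
  list(features = clock$features,
       n_dropped = clock$n_dropped,
       config = clock$config[setdiff(names(clock$config), NULL)],
       sexes = sexes)
}
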