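#' Generate a synthetic cohort with known generative structure
#'
#' Draws a seeded participant table emulating a healthy cohort aged 50-90
#' assessed with the EWGSOP2 motor battery and (optionally) a blood panel.
#' Each feature follows its configured sex-specific linear age trend with
#' independent Gaussian residuals, truncated at physical floors by resampling;
#' SPPB is produced by rounding and clipping a latent continuous score to the
#' 0-12 scale. The returned ground truth mirrors the generative parameters,
#' including the population standardized contribution of every feature, so
#' that model-recovery tests have an exact target.
#'
#' @param config A [generator_config()].
#' @return A list with elements `cohort` (data.frame, one row per participant)
#'   and `ground_truth` (list: per-sex feature table with slopes and
#'   standardized contributions, signal feature list, implied R-squared,
#'   latent accelerations and ager classes).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_participants
  with_local_seed(config$seed, {
    n_f <- round(n * config$sex_ratio)
    sex <- c(rep("F", n_f), rep("M", n - n_f))

    age <- if (config$age_distribution == "uniform") {
      runif(n, config$age_range[1], config$age_range[2])
    } else {
      draw_truncnorm(n, config$age_mean, config$age_sd, config$age_range)
    }

    accel <- if (config$acceleration_sd > 0) {
      rnorm(n, 0, config$acceleration_sd)
    } else {
      rep(0, n)
    }

    cohort <- data.frame(
      id = sprintf("P%04d", seq_len(n)),
      sex = sex,
      age = age,
      stringsAsFactors = FALSE
    )

    feats <- unique(config$ageing_models$feature)
    for (fe in feats) cohort[[fe]] <- NA_real_
    for (s in c("F", "M")) {
      rows <- which(sex == s)
      if (!length(rows)) next
      mod <- config$ageing_models[config$ageing_models$sex == s, ]
      eff_age <- age[rows] + accel[rows]
      for (i in seq_len(nrow(mod))) {
        mu <- mod$intercept50[i] + mod$slope[i] * (eff_age - 50)
        cohort[rows, mod$feature[i]] <-
          draw_floored(mu, mod$sd[i], mod$floor[i])
      }
    }
    cohort$sppb <- pmin(12, pmax(0, round(cohort$sppb)))

    latent_class <- latent_ager_class(accel, config$acceleration_sd > 0)

    if (config$blood_panel) {
      for (mk in unique(config$blood_models$marker)) cohort[[mk]] <- NA_real_
      for (s in c("F", "M")) {
        rows <- which(sex == s)
        if (!length(rows)) next
        bm <- config$blood_models[config$blood_models$sex == s, ]
        for (i in seq_len(nrow(bm))) {
          mu <- rep(bm$mean[i], length(rows))
          sh <- config$class_shifts[[bm$marker[i]]]
          if (!is.null(sh)) mu <- mu + sh[as.character(latent_class[rows])]
          cohort[rows, bm$marker[i]] <-
            draw_floored(mu, bm$sd[i], bm$floor[i])
        }
      }
    }

    contrib <- standardized_contributions(config)
    gt_features <- merge(
      config$ageing_models[, c("feature", "sex", "slope", "sd")],
      contrib, by = c("feature", "sex"), sort = FALSE)
    ground_truth <- list(
      features = gt_features,
      signal_features = lapply(
        stats::setNames(c("F", "M"), c("F", "M")),
        function(s) {
          m <- config$ageing_models
          m$feature[m$sex == s & m$slope != 0]
        }),
      implied_r2 = implied_age_r2(config),
      age_variance = age_variance(config),
      latent_acceleration = stats::setNames(accel, cohort$id),
      latent_class = stats::setNames(as.character(latent_class), cohort$id),
      seed = config$seed
    )
    list(cohort = cohort, ground_truth = ground_truth)
  })
}

# Gaussian draw truncated below at `floor` by resampling (keeps the upper
# tail and bulk undistorted); falls back to clamping after 100 rounds.
draw_floored <- function(mu, sd, floor) {
  x <- rnorm(length(mu), mu, sd)
  for (i in 1:100) {
    bad <- which(x < floor)
    if (!length(bad)) break
    x[bad] <- rnorm(length(bad), mu[bad], sd)
  }
  pmax(x, floor)
}

draw_truncnorm <- function(n, mean, sd, range) {
  x <- rnorm(n, mean, sd)
  for (i in 1:200) {
    bad <- which(x < range[1] | x > range[2])
    if (!length(bad)) break
    x[bad] <- rnorm(length(bad), mean, sd)
  }
  pmin(pmax(x, range[1]), range[2])
}

# Latent ager class by the same 25/75 rank rule the clock uses; random
# balanced-ish classes when no latent acceleration is simulated.
latent_ager_class <- function(accel, has_signal) {
  n <- length(accel)
  lv <- c("decelerated", "normal", "accelerated")
  if (!has_signal) {
    cls <- sample(lv, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    return(factor(cls, levels = lv))
  }
  classify_maa(accel, bounds = c(25, 75))$class
}

#' Summarize a cohort table
#'
#' Per-sex and overall mean, SD and 95 percent confidence interval for every
#' numeric column, in the layout of a cohort descriptives table. SD and CI are
#' `NA` (flagged via `n`) for strata with a single observation.
#'
#' @param cohort A cohort data.frame (as from [generate_cohort()] or
#'   [read_cohort()]).
#' @return A data.frame with columns `stratum`, `variable`, `n`, `mean`, `sd`,
#'   `ci_lo`, `ci_hi`; sex counts are attached as attribute `counts`.
#' @export
summarize_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    stop("`cohort` must be a non-empty data.frame", call. = FALSE)
  }
  num_cols <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  strata <- c(list(overall = rep(TRUE, nrow(cohort))),
              lapply(stats::setNames(c("F", "M"), c("F", "M")),
                     function(s) cohort$sex == s))
  rows <- list()
  for (st in names(strata)) {
    sub <- cohort[strata[[st]], , drop = FALSE]
    if (nrow(sub) == 0) next
    for (v in num_cols) {
      x <- sub[[v]][is.finite(sub[[v]])]
      n <- length(x)
      m <- if (n) mean(x) else NA_real_
      s <- if (n >= 2) sd(x) else NA_real_
      half <- if (n >= 2) qt(0.975, n - 1) * s / sqrt(n) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        stratum = st, variable = v, n = n, mean = m, sd = s,
        ci_lo = m - half, ci_hi = m + half)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "counts") <- table(cohort$sex)
  out
}
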