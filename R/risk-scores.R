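#' Load the published score coefficients
#'
#' Reads the versioned parameter file shipped with the package (or a
#' user-supplied file of the same layout) holding the Ishii sarcopenia chart
#' equations and the Levine PhenoAge coefficients, with citations and units.
#' Coefficients are kept in a human-readable file rather than hard-coded so
#' their provenance is auditable and alternative parameterizations can be
#' swapped in.
#'
#' @param path Optional path to a JSON parameter file; defaults to the
#'   bundled one.
#' @return Nested list of class `score_coefficients`.
#' @export
score_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "score_coefficients.json",
                        package = "muscleclock")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("score coefficient file not found: ", path, call. = FALSE)
  }
  coeffs <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (blk in c("ishii", "phenoage")) {
    if (is.null(coeffs[[blk]])) {
      stop("coefficient file lacks the `", blk, "` block", call. = FALSE)
    }
  }
  structure(coeffs, class = "score_coefficients")
}

#' Ishii sarcopenia screening score and probability
#'
#' Sex-specific linear chart score combining age, handgrip strength and calf
#' circumference; the score increases with age and decreases with grip and
#' calf circumference. Scores above 105 (men) / 120 (women) indicate a high
#' probability of sarcopenia. The score-to-probability mapping is a logistic
#' interpolation of the published chart (10 chart points per logit, centred
#' at the high-risk threshold); the mapping used is flagged in the result.
#'
#' @param age Age in years (positive).
#' @param grip Handgrip strength in kg (positive).
#' @param calf Calf circumference in cm (positive); required.
#' @param sex `"F"` or `"M"` (vectorized).
#' @param coeffs A [score_coefficients()] object.
#' @return Data.frame with columns `score`, `probability`, `high_risk` and
#'   attribute `probability_method`.
#' @export
ishii_score <- function(age, grip, calf, sex, coeffs = score_coefficients()) {
  if (missing(calf) || is.null(calf) || all(is.na(calf))) {
    stop("Ishii requires calf circumference", call. = FALSE)
  }
  n <- max(length(age), length(grip), length(calf), length(sex))
  age <- rep_len(age, n); grip <- rep_len(grip, n)
  calf <- rep_len(calf, n); sex <- rep_len(as.character(sex), n)
  ok <- !is.na(age) & !is.na(grip) & !is.na(calf)
  if (any(age[ok] <= 0 | grip[ok] <= 0 | calf[ok] <= 0)) {
    stop("age, grip and calf circumference must be positive", call. = FALSE)
  }
  if (!all(sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'", call. = FALSE)

  score <- prob <- rep(NA_real_, n)
  high <- rep(NA, n)
  for (s in c("F", "M")) {
    blk <- coeffs$ishii[[if (s == "F") "female" else "male"]]
    i <- sex == s
    tm <- blk$terms
    sc <- tm$age$coef * (age[i] - tm$age$center) +
      tm$grip$coef * (grip[i] - tm$grip$center) +
      tm$calf$coef * (calf[i] - tm$calf$center)
    score[i] <- sc
    prob[i] <- plogis((sc - blk$logistic_midpoint) / blk$logistic_scale)
    high[i] <- sc > blk$high_risk_threshold
  }
  out <- data.frame(score = score, probability = prob, high_risk = high)
  attr(out, "probability_method") <- coeffs$ishii$probability_method
  out
}

#' Levine phenotypic age (PhenoAge) from a blood panel
#'
#' Combines nine blood biomarkers and chronological age into the Gompertz
#' linear predictor `xb`, converts it to the 10-year mortality risk
#' `M = 1 - exp(-exp(xb) (exp(120 gamma) - 1) / gamma)` and inverts the
#' mortality model to the age scale:
#' `PhenoAge = a + ln(-b ln(1 - M)) / c`. PhenoAge is strictly increasing in
#' `xb`, so its rank order equals that of the linear predictor.
#'
#' Panel columns are taken in the cohort-table units (albumin g/dL,
#' creatinine mg/dL, glucose mg/dL, CRP mg/dL, lymphocyte %, MCV fL, RDW %,
#' alkaline phosphatase U/L, WBC 10^3/uL) and converted internally to the
#' units of the published coefficients; CRP enters on the natural-log scale.
#'
#' @param panel Data.frame with columns `albumin`, `creatinine`, `glucose`,
#'   `crp`, `lymphocyte_pct`, `mcv`, `rdw_pct`, `alkaline_phosphatase`,
#'   `wbc`.
#' @param age Chronological ages (years), recycled to `nrow(panel)`.
#' @param coeffs A [score_coefficients()] object.
#' @return Data.frame with columns `xb`, `mortality_risk_10y`, `phenoage`.
#' @export
phenoage <- function(panel, age, coeffs = score_coefficients()) {
  pa <- coeffs$phenoage
  markers <- setdiff(names(pa$terms), "age")
  missing <- setdiff(markers, names(panel))
  if (length(missing)) {
    stop("blood panel is missing biomarker(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(panel)
  age <- rep_len(age, n)
  xb <- rep(pa$intercept, n) + pa$terms$age$coef * age
  for (mk in markers) {
    term <- pa$terms[[mk]]
    val <- as.numeric(panel[[mk]])
    conv <- pa$cohort_unit_conversions[[mk]]
    if (!is.null(conv)) val <- val * conv$factor
    if (identical(term$transform, "log")) {
      if (any(val <= 0, na.rm = TRUE)) {
        stop("`", mk, "` must be positive (entered on the log scale, unit ",
             term$unit, ")", call. = FALSE)
      }
      val <- log(val)
    }
    xb <- xb + term$coef * val
  }
  risk <- 1 - exp(-exp(xb) * (exp(pa$gamma * pa$time_months) - 1) / pa$gamma)
  tr <- pa$transform
  pheno <- tr$a + log(-tr$b * log(1 - risk)) / tr$c
  data.frame(xb = xb, mortality_risk_10y = risk, phenoage = pheno)
}

#' Phenotypic age acceleration (PhenoAA)
#'
#' Residuals of PhenoAge regressed on chronological age; same contract as
#' [compute_age_acceleration()], which it shares.
#'
#' @param phenoages PhenoAge values (years).
#' @param chronological Chronological ages (years).
#' @return Numeric vector of residuals (years).
#' @export
pheno_age_acceleration <- function(phenoages, chronological) {
  compute_age_acceleration(phenoages, chronological)
}
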