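test_that("the Ishii chart vanishes at its centering values", {
  res <- ishii_score(age = 64, grip = 50, calf = 42, sex = "M")
  expect_equal(res$score, 0)
  expect_false(res$high_risk)
  resf <- ishii_score(age = 64, grip = 34, calf = 42, sex = "F")
  expect_equal(resf$score, 0)
  expect_false(resf$high_risk)
})

test_that("the Ishii score is monotone in age, grip and calf", {
  ages <- seq(50, 90, by = 2)
  s_age <- ishii_score(ages, grip = 30, calf = 36, sex = "M")
  expect_true(all(diff(s_age$score) > 0))
  expect_true(all(diff(s_age$probability) > 0))
  grips <- seq(15, 55, by = 2)
  s_grip <- ishii_score(70, grips, calf = 36, sex = "F")
  expect_true(all(diff(s_grip$score) < 0))
  expect_true(all(diff(s_grip$probability) < 0))
  calves <- seq(28, 44, by = 1)
  s_calf <- ishii_score(70, grip = 30, calves, sex = "M")
  expect_true(all(diff(s_calf$score) < 0))
})

test_that("high risk is flagged strictly above the published thresholds", {
  # solve for the age that yields a given male score with grip/calf fixed
  grip <- 30; calf <- 36
  base <- ishii_score(64, grip, calf, "M")$score
  age_for <- function(target) 64 + (target - base) / 0.62
  expect_true(ishii_score(age_for(106), grip, calf, "M")$high_risk)
  expect_false(ishii_score(age_for(105), grip, calf, "M")$high_risk)
  expect_false(ishii_score(age_for(104), grip, calf, "M")$high_risk)
})

test_that("Ishii requires calf circumference and valid inputs", {
  expect_error(ishii_score(70, 30, NA, "M"), "calf circumference")
  expect_error(ishii_score(70, -3, 36, "M"), "positive")
  expect_error(ishii_score(70, 30, 36, "X"), "sex")
})

test_that("PhenoAge matches an independent implementation to 1e-6 years", {
  panels <- random_panels(100, seed = 314)
  ages <- withr::with_seed(315, runif(100, 50, 90))
  res <- phenoage(panels, ages)
  expect_equal(res$phenoage, phenoage_oracle(panels, ages), tolerance = 1e-6)
  expect_true(all(res$mortality_risk_10y > 0 & res$mortality_risk_10y < 1))
  # deterministic
  expect_identical(res, phenoage(panels, ages))
})

test_that("PhenoAge is monotone in its linear predictor and in age", {
  panels <- random_panels(50, seed = 316)
  res <- phenoage(panels, age = 70)
  expect_equal(order(res$phenoage), order(res$xb))
  one <- panels[1, ]
  ages <- seq(50, 90, by = 5)
  ph <- phenoage(one[rep(1, length(ages)), ], ages)
  expect_true(all(diff(ph$phenoage) > 0))
})

test_that("missing biomarkers are reported by name", {
  p <- random_panels(5)
  p$rdw_pct <- NULL
  expect_error(phenoage(p, 70), "rdw_pct")
  p2 <- random_panels(5)
  p2$crp[2] <- -1
  expect_error(phenoage(p2, 70), "crp")
})

test_that("PhenoAA shares the residualization contract with MAA", {
  age <- c(50, 60, 70)
  expect_equal(pheno_age_acceleration(age, age), rep(0, 3), tolerance = 1e-12)
  expect_equal(pheno_age_acceleration(c(60, 72, 80), age),
               c(-2 / 3, 4 / 3, -2 / 3), tolerance = 1e-10)
  x <- withr::with_seed(9, runif(30, 40, 90))
  y <- withr::with_seed(10, x + rnorm(30, 0, 5))
  expect_lt(abs(sum(pheno_age_acceleration(y, x))), 1e-10)
})

test_that("score coefficients load from the versioned parameter file", {
  co <- score_coefficients()
  expect_s3_class(co, "score_coefficients")
  expect_equal(co$ishii$male$terms$age$coef, 0.62)
  expect_equal(co$phenoage$terms$rdw_pct$coef, 0.3306)
  expect_match(co$phenoage$citation, "Levine")
  expect_error(score_coefficients("/nonexistent.json"), "not found")
})
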