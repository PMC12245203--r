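test_that("identical config and seed reproduce the cohort byte for byte", {
  cfg <- generator_config(n_participants = 215, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$ground_truth, b$ground_truth)
  c2 <- generate_cohort(generator_config(n_participants = 215, seed = 8))
  expect_false(identical(a$cohort, c2$cohort))
})

test_that("invalid generator settings are rejected with the field named", {
  expect_error(generator_config(age_range = c(90, 50)), "age_range")
  expect_error(generator_config(sex_ratio = 1.2), "sex_ratio")
  am <- default_ageing_models()
  am$sd[am$feature == "tug"] <- 0
  expect_error(generator_config(ageing_models = am), "tug")
  expect_error(generator_config(target_r2 = 1.5), "target_r2")
})

test_that("zero slopes leave features uncorrelated with age", {
  am <- default_ageing_models()
  am$slope <- 0
  cfg <- generator_config(n_participants = 500, ageing_models = am,
                          target_r2 = NULL, blood_panel = FALSE, seed = 21)
  g <- generate_cohort(cfg)
  for (fe in clock_features()) {
    expect_lt(abs(cor(g$cohort[[fe]], g$cohort$age)), 0.2)
  }
  gt <- g$ground_truth
  expect_identical(gt$signal_features$F, character(0))
  expect_true(all(gt$features$contribution == 0))
})

test_that("feature-age correlation matches the closed-form value", {
  # corr = slope * sd_age / sqrt(slope^2 sd_age^2 + sd_noise^2); with TUG
  # slope 0.05 s/yr and noise SD 0.77 s on uniform ages 50-90 this is ~0.6.
  am <- default_ageing_models()
  am$slope <- 0
  am$slope[am$feature == "tug"] <- 0.05
  am$sd[am$feature == "tug"] <- 0.77
  cfg <- generator_config(n_participants = 2000, sex_ratio = 1,
                          ageing_models = am, target_r2 = NULL,
                          blood_panel = FALSE, seed = 31)
  g <- generate_cohort(cfg)
  sd_age <- sqrt(40^2 / 12)
  closed <- 0.05 * sd_age / sqrt(0.05^2 * sd_age^2 + 0.77^2)
  expect_equal(cor(g$cohort$tug, g$cohort$age), closed, tolerance = 0.05 / closed)
  expect_equal(unname(g$ground_truth$implied_r2["F"]), closed^2,
               tolerance = 1e-10)
})

test_that("marginal means and SDs track the configured models", {
  cfg <- generator_config(n_participants = 2000, sex_ratio = 0.5,
                          target_r2 = NULL, seed = 41)
  g <- generate_cohort(cfg)
  mean_age <- mean(cfg$age_range)
  for (s in c("F", "M")) {
    sub <- g$cohort[g$cohort$sex == s, ]
    mod <- cfg$ageing_models[cfg$ageing_models$sex == s, ]
    for (fe in c("handgrip", "tug", "six_mwt", "weight")) {
      row <- mod[mod$feature == fe, ]
      expected <- row$intercept50 + row$slope * (mean_age - 50)
      total_sd <- sqrt(row$slope^2 * 40^2 / 12 + row$sd^2)
      se <- total_sd / sqrt(nrow(sub))
      expect_lt(abs(mean(sub[[fe]]) - expected), 3 * se + 0.02 * total_sd)
    }
  }
})

test_that("generated cohorts respect physical ranges and unique ids", {
  g <- generate_cohort(generator_config(n_participants = 300, seed = 5))
  co <- g$cohort
  expect_false(anyDuplicated(co$id) > 0)
  expect_true(all(co$age >= 50 & co$age <= 90))
  expect_true(all(co$sppb >= 0 & co$sppb <= 12))
  expect_true(all(co$sppb == round(co$sppb)))
  pos_cols <- c(clock_features()[clock_features() != "sppb"],
                "weight", "height", "wbc", "crp")
  for (v in pos_cols) expect_true(all(co[[v]] > 0), label = v)
})

test_that("latent ager classes shift blood markers when configured", {
  cfg <- generator_config(
    n_participants = 900, sex_ratio = 0.5, seed = 61,
    acceleration_sd = 4,
    class_shifts = list(wbc = c(decelerated = -0.8, normal = 0,
                                accelerated = 0.8)))
  g <- generate_cohort(cfg)
  cls <- g$ground_truth$latent_class[g$cohort$id]
  m_dec <- mean(g$cohort$wbc[cls == "decelerated"])
  m_acc <- mean(g$cohort$wbc[cls == "accelerated"])
  expect_gt(m_acc - m_dec, 0.8)  # 1.6 configured minus sampling noise
})

test_that("cohort summaries reproduce hand-computed statistics", {
  one <- data.frame(id = "a", sex = "F", age = 60, handgrip = 25)
  s1 <- summarize_cohort(one)
  row <- s1[s1$stratum == "overall" & s1$variable == "handgrip", ]
  expect_equal(row$mean, 25)
  expect_equal(row$n, 1)
  expect_true(is.na(row$sd))

  two <- data.frame(id = c("a", "b"), sex = c("F", "F"), age = c(60, 61),
                    x = c(1, 3))
  s2 <- summarize_cohort(two)
  row <- s2[s2$stratum == "overall" & s2$variable == "x", ]
  expect_equal(row$mean, 2)
  expect_equal(row$sd, sqrt(2))

  mc <- withr::with_seed(17, data.frame(id = as.character(1:1000),
                                        sex = "M", age = 70,
                                        z = rnorm(1000)))
  s3 <- summarize_cohort(mc)
  row <- s3[s3$stratum == "overall" & s3$variable == "z", ]
  expect_lt(abs(row$mean), 0.1)
  expect_lt(abs(row$sd - 1), 0.1)

  expect_error(summarize_cohort(data.frame()), "non-empty")
})
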