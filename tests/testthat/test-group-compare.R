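toy_design <- function() {
  status <- rep(rep(c("decelerated", "normal", "accelerated"), each = 4), 2)
  sex <- rep(c("F", "M"), each = 12)
  list(status = status, sex = sex)
}

test_that("identical cell means yield zero F and p of one", {
  d <- toy_design()
  outcome <- 10 + rep(c(-0.3, -0.1, 0.1, 0.3), 6)  # every cell mean is 10
  res <- two_way_anova(outcome, d$status, d$sex)
  expect_equal(res$effects$F, rep(0, 3), tolerance = 1e-10)
  expect_equal(res$effects$p, rep(1, 3), tolerance = 1e-10)
})

test_that("the sex main effect matches hand-computed sums of squares", {
  d <- toy_design()
  jitter <- rep(c(-0.3, -0.1, 0.1, 0.3), 6)
  outcome <- ifelse(d$sex == "F", 0, 1) + jitter
  res <- two_way_anova(outcome, d$status, d$sex)

  # balanced design: SS_sex = n/2 * sum over sexes of (mean_s - grand)^2 ...
  grand <- mean(outcome)
  ss_sex <- sum(tapply(outcome, d$sex, function(x) {
    length(x) * (mean(x) - grand)^2
  }))
  ss_status <- sum(tapply(outcome, d$status, function(x) {
    length(x) * (mean(x) - grand)^2
  }))
  cellmean <- ave(outcome, d$status, d$sex)
  ss_resid <- sum((outcome - cellmean)^2)
  f_sex_hand <- (ss_sex / 1) / (ss_resid / (24 - 6))
  eff <- res$effects
  expect_equal(eff$F[eff$term == "sex"], f_sex_hand, tolerance = 1e-10)
  expect_equal(eff$F[eff$term == "status"], 0, tolerance = 1e-10)
})

test_that("a constant sex vector reduces to hand-computed one-way ANOVA", {
  status <- rep(c("a", "b", "c"), times = c(5, 7, 6))
  outcome <- withr::with_seed(2, rnorm(18, 50, 4) +
                                ifelse(status == "c", 3, 0))
  res <- two_way_anova(outcome, status, rep("F", 18))
  grand <- mean(outcome)
  ss_b <- sum(tapply(outcome, status, function(x) {
    length(x) * (mean(x) - grand)^2
  }))
  ss_w <- sum((outcome - ave(outcome, status))^2)
  f_hand <- (ss_b / 2) / (ss_w / 15)
  expect_equal(res$effects$F[res$effects$term == "status"], f_hand,
               tolerance = 1e-10)
  expect_false("sex" %in% res$effects$term)
})

test_that("Bonferroni adjustment is the capped multiplication rule", {
  d <- toy_design()
  outcome <- withr::with_seed(3,
    rnorm(24, 10, 1) + ifelse(d$status == "accelerated", 1.2, 0))
  res <- two_way_anova(outcome, d$status, d$sex)
  pw <- res$pairwise
  expect_equal(pw$adj_p, pmin(1, pw$raw_p * 3), tolerance = 1e-12)
  expect_true(all(pw$adj_p >= pw$raw_p - 1e-15))
  expect_true(all(pw$adj_p <= 1))
})

test_that("constant outcomes report F = 0 with p = 1", {
  d <- toy_design()
  res <- two_way_anova(rep(7, 24), d$status, d$sex)
  expect_true(all(res$effects$F == 0))
  expect_true(all(res$effects$p == 1))
  expect_true(all(res$pairwise$adj_p == 1))
})

test_that("empty design cells are reported by name", {
  status <- c(rep("a", 4), rep("b", 4))
  sex <- c(rep("F", 4), rep("M", 4))  # a:M and b:F empty
  expect_error(two_way_anova(rnorm(8), status, sex), "a:M")
})

test_that("group means are simple averages with SEM", {
  d <- toy_design()
  outcome <- seq_len(24)
  res <- two_way_anova(outcome, d$status, d$sex)
  m <- res$means
  dec <- m[m$stratum == "overall" & m$group == "decelerated", ]
  x <- outcome[d$status == "decelerated"]
  expect_equal(dec$mean, mean(x))
  expect_equal(dec$sem, sd(x) / sqrt(length(x)))
})

test_that("correlations reproduce hand-computed values", {
  x <- c(1, 2, 3, 4)
  cm <- pearson_correlations(data.frame(x = x, y = 2 * x + 3,
                                        z = -x, w = c(1, 3, 2, 4)))
  r <- cm$overall$r
  expect_equal(unname(r["x", "y"]), 1, tolerance = 1e-12)
  expect_equal(unname(r["x", "z"]), -1, tolerance = 1e-12)
  expect_equal(unname(r["x", "w"]), 0.8, tolerance = 1e-12)
  expect_true(all(diag(r) == 1))
  expect_equal(r, t(r))
})

test_that("short or stratified inputs are handled pair by pair", {
  d <- data.frame(a = c(1, 2, NA, NA), b = c(2, 1, NA, NA), c = 1:4)
  cm <- pearson_correlations(d)
  expect_true(is.na(cm$overall$r["a", "b"]))  # only 2 complete pairs
  expect_equal(cm$overall$n["a", "b"], 2L)
  strat <- pearson_correlations(
    data.frame(x = c(1:5, 1:5), y = c(2 * (1:5), 5:1)),
    stratify_by = rep(c("F", "M"), each = 5))
  expect_equal(unname(strat$F$r["x", "y"]), 1, tolerance = 1e-12)
  expect_equal(unname(strat$M$r["x", "y"]), -1, tolerance = 1e-12)
})

test_that("percent differences follow the reference convention", {
  expect_equal(percent_difference(4, 3), -25)
  expect_equal(percent_difference(10, 10), 0)
  expect_error(percent_difference(0, 5), "non-zero")
})
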