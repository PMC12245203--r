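make_x <- function(n, p, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    scale(x, scale = apply(x, 2, function(c) sqrt(mean((c - mean(c))^2))))
  })
}

test_that("pure-noise age yields near-zero coefficients and no skill", {
  # any single dataset can carry a spurious in-sample correlation of order
  # sd(age)/sqrt(n), so the null claim is checked on coefficients averaged
  # over replicate datasets as well as per-dataset test skill
  reps <- lapply(1:4, function(r) {
    x <- make_x(200, 5, seed = 2 * r)
    age <- withr::with_seed(3 * r + 1, runif(200, 50, 90))
    fit_permuted_elastic_net(x, age, tiny_clock_config(20))
  })
  for (fit in reps) expect_lte(fit$r2_mean, 0.05)
  mean_beta <- rowMeans(vapply(reps, `[[`, numeric(5), "coef_mean"))
  expect_true(all(abs(mean_beta) < 0.2))
})

test_that("a noiseless linear signal is recovered almost exactly", {
  x <- make_x(200, 5, seed = 4)
  age <- 60 + 2 * x[, 1]
  fit <- fit_permuted_elastic_net(x, age, tiny_clock_config(10))
  expect_lt(abs(fit$coef_mean["f1"] - 2), 0.1)
  expect_true(all(abs(fit$coef_mean[-1]) < 0.05))
  expect_gt(fit$r2_mean, 0.99)
})

test_that("the permutation procedure is deterministic under a base seed", {
  x <- make_x(120, 4, seed = 5)
  age <- 65 + 1.5 * x[, 2] + withr::with_seed(6, rnorm(120, 0, 4))
  f1 <- fit_permuted_elastic_net(x, age, tiny_clock_config(8, base_seed = 77))
  f2 <- fit_permuted_elastic_net(x, age, tiny_clock_config(8, base_seed = 77))
  expect_identical(f1, f2)
  f3 <- fit_permuted_elastic_net(x, age, tiny_clock_config(8, base_seed = 78))
  expect_false(identical(f1$coef_mean, f3$coef_mean))
})

test_that("fit summaries carry one record per permutation and valid metrics", {
  x <- make_x(100, 3, seed = 7)
  age <- 60 + x[, 1] + withr::with_seed(8, rnorm(100, 0, 3))
  fit <- fit_permuted_elastic_net(x, age, tiny_clock_config(12))
  expect_equal(nrow(fit$records), 12)
  expect_true(all(fit$records$rmse >= 0))
  expect_true(all(fit$coef_sd >= 0))
  expect_true(all(fit$records$l1_ratio %in% c(0.5, 1)))
  expect_equal(fit$records$seed, 42 + 1:12)
})

test_that("samples too small for the split and folds are rejected", {
  x <- make_x(8, 2, seed = 9)
  expect_error(
    fit_permuted_elastic_net(x, rnorm(8, 60), tiny_clock_config(2)),
    "too small")
  expect_error(
    fit_permuted_elastic_net(x[1:5, ], rnorm(8, 60), tiny_clock_config(2)),
    "match")
})

test_that("a fixed user alpha grid is honoured by the selection step", {
  x <- make_x(80, 3, seed = 10)
  age <- 60 + 2 * x[, 1] + withr::with_seed(11, rnorm(80, 0, 2))
  cfg <- clock_config(n_permutations = 4, alpha_grid = 1e-6,
                      l1_ratio_grid = 0.5, base_seed = 1)
  fit <- fit_permuted_elastic_net(x, age, cfg)
  expect_true(all(fit$records$alpha == 1e-6))
  expect_true(all(fit$records$l1_ratio == 0.5))
})
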