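small_clock <- function(n = 200, seed = 77, perms = 8, base_seed = 5) {
  g <- signal_cohort(n = n, seed = seed)
  build_clock(g$cohort, tiny_clock_config(perms, base_seed = base_seed))
}

test_that("the end-to-end clock is reproducible under a fixed seed", {
  a <- small_clock()
  b <- small_clock()
  expect_identical(maa_table(a), maa_table(b))
  expect_identical(clock_report(a)$sexes$F$phase1$records,
                   clock_report(b)$sexes$F$phase1$records)
})

test_that("MAA is orthogonal to chronological age within each sex", {
  clock <- small_clock()
  for (s in c("F", "M")) {
    maa <- clock$sexes[[s]]$maa
    expect_lt(abs(mean(maa$maa)), 1e-10)
    expect_lt(abs(cor(maa$maa, maa$age)), 1e-10)
  }
})

test_that("a single-sex cohort fits that stratum only", {
  g <- signal_cohort(n = 200, seed = 78)
  fem <- g$cohort[g$cohort$sex == "F", ]
  clock <- build_clock(fem, tiny_clock_config(6))
  expect_named(clock$sexes, "F")
  expect_null(clock$sexes$M)
})

test_that("tests that worsen with age earn positive weights and vice versa", {
  clock <- small_clock(n = 300, seed = 79, perms = 10)
  for (s in c("F", "M")) {
    cm <- clock$sexes[[s]]$phase1$coef_mean
    expect_gt(cm["tug"], 0)
    expect_gt(cm["five_tsts"], 0)
    expect_lt(cm["handgrip"], 0)
    expect_lt(cm["six_mwt"], 0)
  }
})

test_that("undersized strata and missing columns are reported by name", {
  g <- signal_cohort(n = 200, seed = 80)
  tiny <- g$cohort[c(which(g$cohort$sex == "F"),
                     which(g$cohort$sex == "M")[1:8]), ]
  expect_error(build_clock(tiny, tiny_clock_config(4)), "stratum M")
  no_tug <- g$cohort[, setdiff(names(g$cohort), "tug")]
  expect_error(build_clock(no_tug, tiny_clock_config(4)), "tug")
})

test_that("rows with missing features are dropped with a logged count", {
  g <- signal_cohort(n = 200, seed = 81)
  co <- g$cohort
  co$handgrip[c(3, 10)] <- NA
  expect_message(clock <- build_clock(co, tiny_clock_config(6)),
                 "dropping 2")
  expect_equal(clock$n_dropped, 2)
  expect_equal(nrow(maa_table(clock)), 198)
})

test_that("pooled residualization classifies across sexes jointly", {
  g <- signal_cohort(n = 200, seed = 82)
  clock <- build_clock(g$cohort,
                       tiny_clock_config(6, pooled_residualization = TRUE))
  tab <- maa_table(clock)
  expect_equal(unname(table(tab$class)["decelerated"]), 50L)
  expect_identical(clock$sexes$F$cutoffs, clock$sexes$M$cutoffs)
  # pooled residuals are orthogonal to age overall
  expect_lt(abs(mean(tab$maa)), 1e-10)
  expect_lt(abs(cor(tab$maa, tab$age)), 1e-10)
})
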