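# Small configurations used across tests to keep runtimes modest; the
# defaults (100 permutations, full grids) are exercised in the pipeline and
# acceptance tests.

tiny_clock_config <- function(n_permutations = 10, base_seed = 42, ...) {
  clock_config(n_permutations = n_permutations,
               l1_ratio_grid = c(0.5, 1),
               base_seed = base_seed, ...)
}

# Cohort with a clear age signal in both sexes, for clock-level tests.
signal_cohort <- function(n = 200, seed = 123, target_r2 = 0.4) {
  generate_cohort(generator_config(n_participants = n, sex_ratio = 0.5,
                                   target_r2 = target_r2, seed = seed))
}

# Random in-range blood panels in cohort-table units.
random_panels <- function(n, seed = 99) {
  withr::with_seed(seed, data.frame(
    albumin = runif(n, 3.5, 5.0),
    creatinine = runif(n, 0.5, 1.4),
    glucose = runif(n, 70, 130),
    crp = runif(n, 0.02, 1.5),
    lymphocyte_pct = runif(n, 15, 50),
    mcv = runif(n, 75, 100),
    rdw_pct = runif(n, 11, 17),
    alkaline_phosphatase = runif(n, 30, 130),
    wbc = runif(n, 3, 10)
  ))
}

# Independent arithmetic implementation of the Levine PhenoAge formulas,
# written directly from the published coefficient table (units: albumin g/L,
# creatinine umol/L, glucose mmol/L, CRP ln mg/dL, lymphocyte %, MCV fL,
# RDW %, ALP U/L, WBC 10^3/uL, age years).
phenoage_oracle <- function(panel, age) {
  xb <- -19.9067 +
    (-0.0336) * (panel$albumin * 10) +
    0.0095 * (panel$creatinine * 88.4017) +
    0.1953 * (panel$glucose * 0.0555) +
    0.0954 * log(panel$crp) +
    (-0.0120) * panel$lymphocyte_pct +
    0.0268 * panel$mcv +
    0.3306 * panel$rdw_pct +
    0.00188 * panel$alkaline_phosphatase +
    0.0554 * panel$wbc +
    0.0804 * age
  gamma <- 0.0076927
  m <- 1 - exp(-exp(xb) * (exp(gamma * 120) - 1) / gamma)
  141.50225 + log(-0.00553 * log(1 - m)) / 0.090165
}
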