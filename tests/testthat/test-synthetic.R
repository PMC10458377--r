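test_that("generation is deterministic in the seed", {
  pw <- planted_week_effect_design(n_tbi = 30, n_sham = 30, n_experiments = 2)
  a <- generate_cohort(pw$design, pw$effects, seed = 5)
  b <- generate_cohort(pw$design, pw$effects, seed = 5)
  expect_identical(a$cohort$measurements, b$cohort$measurements)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(pw$design, pw$effects, seed = 6)
  expect_false(identical(a$cohort$measurements, c$cohort$measurements))

  # byte-identical files under the same seed
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(a$cohort, d1)
  write_cohort(b$cohort, d2)
  expect_identical(readLines(file.path(d1, "measurements.csv")),
                   readLines(file.path(d2, "measurements.csv")))
})

test_that("a null design separates groups only by sampling noise", {
  blocks <- tibble::tibble(
    experiment_id = "E1", n_tbi = 500, n_sham = 500, drop_height_in = 42,
    n_hits = 5L, schedule = "5_in_5_days", age_weeks = 8L,
    treatment = "none", treatment_route = "none",
    battery = list(c("MWM:H1:W2", "EPM:O:W2")))
  design <- design_from_blocks(blocks)
  reject <- 0L
  for (seed in 1:10) {
    g <- generate_cohort(design, null_effects(), seed = seed)
    wide <- cohort_table(g$cohort)
    p <- t.test(wide[["MWM:H1:W2"]] ~ wide$group)$p.value
    if (p < 0.01) reject <- reject + 1L
  }
  expect_lte(reject, 1L)  # ~0.01 type-I rate over 10 seeds
})

test_that("a planted 3-SD effect is nearly perfectly discriminable", {
  blocks <- tibble::tibble(
    experiment_id = "E1", n_tbi = 150, n_sham = 150, drop_height_in = 42,
    n_hits = 5L, schedule = "5_in_5_days", age_weeks = 8L,
    treatment = "none", treatment_route = "none",
    battery = list("MWM:H1:W2"))
  eff <- effect_spec(level3 = "MWM:H", week = 2L, baseline = 100, sd = 10,
                     effect = 3)
  g <- generate_cohort(design_from_blocks(blocks), eff, seed = 2)
  res <- bootstrap_auc(cohort_table(g$cohort), "MWM:H1:W2", B = 25, seed = 2)
  expect_gte(res$auc_mean, 0.95)  # Gaussian overlap at 3 SD: ~Phi(3/sqrt(2))
})

test_that("planted effects always shift TBI mice toward the bad direction", {
  battery <- c("MWM:H1:W2", "MWM:PF1:W2", "EPM:O:W2", "FST:D1:W2",
               "Rota:D2:W2", "OF:C:C:W2")
  blocks <- tibble::tibble(
    experiment_id = "E1", n_tbi = 400, n_sham = 400, drop_height_in = 42,
    n_hits = 5L, schedule = "5_in_5_days", age_weeks = 8L,
    treatment = "none", treatment_route = "none", battery = list(battery))
  reg <- default_registry()
  fams <- unique(resolve_codes(battery, reg)$level3)
  eff <- effect_spec(level3 = fams, week = 2L,
                     baseline = rep(200, length(fams)), sd = rep(10, length(fams)),
                     effect = rep(1.5, length(fams)))
  g <- generate_cohort(design_from_blocks(blocks), eff, seed = 4)
  wide <- cohort_table(g$cohort)
  for (code in battery) {
    dir <- resolve_codes(code, reg)$good_direction
    delta <- mean(wide[[code]][wide$group == "TBI"]) -
      mean(wide[[code]][wide$group == "sham"])
    # lower_better families worsen upward, higher_better downward
    if (dir == "lower_better") expect_gt(delta, 0) else expect_lt(delta, 0)
  }
})

test_that("loss of consciousness increases with drop height, floored at zero", {
  blocks <- tibble::tibble(
    experiment_id = c("E1", "E2"), n_tbi = c(200, 0), n_sham = c(0, 200),
    drop_height_in = c(60, 0), n_hits = 5L, schedule = "5_in_5_days",
    age_weeks = 8L, treatment = "none", treatment_route = "none",
    battery = list("LOC:1:W0", "LOC:1:W0"))
  g <- generate_cohort(design_from_blocks(blocks), null_effects(), seed = 3)
  wide <- cohort_table(g$cohort)
  expect_true(all(wide[["LOC:1:W0"]] >= 0))
  expect_gt(mean(wide[["LOC:1:W0"]][wide$group == "TBI"]),
            mean(wide[["LOC:1:W0"]][wide$group == "sham"]) + 20)
})

test_that("the design fixture reproduces the mouse-characteristics margins", {
  fx <- fixture_design()
  mice <- fx$mice
  expect_equal(nrow(mice), 1203L)
  expect_equal(sum(mice$group == "TBI"), 675L)
  expect_equal(sum(mice$group == "sham"), 528L)
  expect_equal(length(unique(mice$experiment_id)), 58L)
  # drop heights
  expect_equal(as.integer(table(mice$drop_height_in[mice$group == "TBI"])[
    c("28", "42", "46", "50", "60")]), c(218L, 319L, 35L, 63L, 40L))
  # procedure schedules (both groups)
  sched <- table(mice$schedule, mice$group)
  expect_equal(unname(sched["5_in_5_days", c("TBI", "sham")]), c(301L, 266L))
  expect_equal(unname(sched["7_in_9_days", c("TBI", "sham")]), c(102L, 76L))
  expect_equal(unname(sched["6to13_in_5_days", c("TBI", "sham")]), c(0L, 8L))
  # ages
  expect_equal(as.integer(table(mice$age_weeks)[c("5", "8", "12", "28")]),
               c(101L, 1008L, 47L, 47L))
  # treatments
  trt <- table(mice$treatment)
  expect_equal(as.integer(trt[c("none", "enrichment", "memantine", "cis_p_tau")]),
               c(550L, 149L, 114L, 47L))
})

test_that("the fixture reproduces every nonzero measurement-design cell", {
  fx <- fixture_design()
  reg <- default_registry()
  counts <- dplyr::count(fx$assignments, outcome_code)
  merged <- dplyr::left_join(reg, counts, by = c(code = "outcome_code"))
  expect_true(all(merged$n == merged$design_n))
  # and assigns nothing outside the design
  expect_setequal(unique(fx$assignments$outcome_code), reg$code)
})

test_that("the planted week profile is concave with the stated peak", {
  pw <- planted_week_effect_design(peak_week = 13, amplitude = 1.5,
                                   n_tbi = 20, n_sham = 20, n_experiments = 2)
  eff <- pw$effects
  mwm <- eff[eff$level3 == "MWM:H", ]
  e <- setNames(mwm$effect, mwm$week)
  expect_gt(e[["13"]], e[["2"]])
  expect_gt(e[["13"]], e[["28"]])
  expect_equal(e[["13"]], 1.5)
  # zero amplitude -> flat profile
  flat <- planted_week_effect_design(amplitude = 0, n_tbi = 20, n_sham = 20,
                                     n_experiments = 2)$effects
  expect_true(all(flat$effect == 0))
})
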