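test_that("AUC equals the pair-counting statistic with the tie convention", {
  expect_equal(auc_pairs(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_pairs(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(auc_pairs(rep(1, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auc_pairs(1:3, c(1, 1, 1)), "both classes")

  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # ties likely
    expect_equal(auc_pairs(s, y), brute_auc(s, y))
    # invariance under strictly increasing transforms
    expect_equal(auc_pairs(exp(3 * s), y), auc_pairs(s, y))
    # complement under score negation (no-ties case)
    s2 <- rnorm(n)
    expect_equal(auc_pairs(s2, y) + auc_pairs(-s2, y), 1)
  }
})

test_that("the logistic fit is guarded, converges, and ranks separably", {
  # intercept-only equivalent: balanced labels, uninformative constant-free fit
  set.seed(4)
  x <- matrix(rnorm(200), 100, 2)
  y <- rep(c(0, 1), 50)
  fit <- fit_logistic(x, y)
  expect_length(fit$coefficients, 3L)

  # planted 2-SD separation: in-sample AUC above the Gaussian-overlap level
  d <- make_classif_data(200, p = 1, effect = 2, seed = 5)
  fit2 <- fit_logistic(as.matrix(d[, 1]), d$group)
  expect_gt(auc_pairs(fit2$predict(as.matrix(d[, 1])),
                      as.integer(d$group == "TBI")), 0.9)

  # guard: 15 mice with one behavioral predictor plus one adjustment covariate
  d15 <- make_classif_data(15, p = 1, seed = 6)
  expect_error(bootstrap_auc(d15, "MWM:H1:W2"), "not run")
  expect_silent(fit_logistic(as.matrix(d15[, 1]), d15$group))  # 15 >= 10 x 1

  # guard monotonicity: any superset is refused at the same n
  d25 <- make_classif_data(25, p = 3, seed = 7)
  expect_error(bootstrap_auc(d25, c("MWM:H1:W2", "MWM:H2:W2")), "not run")
  expect_error(bootstrap_auc(d25, c("MWM:H1:W2", "MWM:H2:W2", "MWM:H3:W2")),
               "not run")

  # complete separation: iteration cap keeps the ranking usable
  xs <- matrix(c(rep(0, 10), rep(10, 10)), ncol = 1)
  ys <- rep(c(0, 1), each = 10)
  fit3 <- fit_logistic(xs, ys)
  expect_equal(auc_pairs(fit3$predict(xs), ys), 1)
})

test_that("bootstrapped AUC is calibrated, sensitive and deterministic", {
  # null features: mean near chance
  null <- make_classif_data(300, p = 1, effect = 0, seed = 8)
  rn <- bootstrap_auc(null, "MWM:H1:W2", B = 25, seed = 8)
  expect_lt(abs(rn$auc_mean - 0.5), 0.08)
  expect_equal(rn$n_total, 300L)
  expect_equal(rn$n_tbi + rn$n_sham, rn$n_total)

  # planted 3-SD effect: near-perfect discrimination
  strong <- make_classif_data(300, p = 1, effect = 3, seed = 9)
  rs <- bootstrap_auc(strong, "MWM:H1:W2", B = 25, seed = 9)
  expect_gte(rs$auc_mean, 0.95)

  # fixed seed reproduces the result exactly
  again <- bootstrap_auc(strong, "MWM:H1:W2", B = 25, seed = 9)
  expect_identical(rs, again)
  other <- bootstrap_auc(strong, "MWM:H1:W2", B = 25, seed = 10)
  expect_false(identical(rs$auc_mean, other$auc_mean))
})

test_that("bootstrap null calibration holds across replications", {
  means <- vapply(1:12, function(s) {
    d <- make_classif_data(120, p = 1, effect = 0, seed = 100 + s)
    bootstrap_auc(d, "MWM:H1:W2", B = 25, seed = s)$auc_mean
  }, numeric(1))
  expect_gt(mean(means), 0.42)
  expect_lt(mean(means), 0.58)
})

test_that("cross-validated AUC agrees with the bootstrap on strong effects", {
  strong <- make_classif_data(300, p = 1, effect = 2, seed = 11)
  rb <- bootstrap_auc(strong, "MWM:H1:W2", B = 25, seed = 11)
  rc <- cv_auc(strong, "MWM:H1:W2", folds = 10, seed = 11)
  expect_lt(abs(rb$auc_mean - rc$auc_mean), 0.05)
  expect_equal(rc$iterations_used, 10L)

  null <- make_classif_data(200, p = 1, effect = 0, seed = 12)
  rn <- cv_auc(null, "MWM:H1:W2", seed = 12)
  expect_lt(abs(rn$auc_mean - 0.5), 0.1)

  # too few mice per class for the folds
  tiny <- make_classif_data(120, p = 1, seed = 13, balance = 0.05)
  expect_error(cv_auc(tiny, "MWM:H1:W2", folds = 10), "folds infeasible")
})

test_that("quadratic time trends locate the optimal week", {
  # exact parabola through three points: vertex at week 15
  tt <- fit_time_trend(tibble::tibble(week = c(2, 13, 28),
                                      auc_mean = c(0.6, 0.9, 0.6)))
  expect_equal(tt$optimal_week, 15, tolerance = 1e-9)

  # increasing linear trend -> boundary rule picks the last week
  tt2 <- fit_time_trend(tibble::tibble(week = c(2, 13, 28),
                                       auc_mean = c(0.6, 0.7, 0.8)))
  expect_equal(tt2$optimal_week, 28)

  # flat AUC -> flat curve, earliest boundary week by the tie rule
  tt3 <- fit_time_trend(tibble::tibble(week = c(2, 13, 28),
                                       auc_mean = c(0.7, 0.7, 0.7)))
  expect_lt(max(abs(tt3$coefficients[c("b", "c")])), 1e-9)
  expect_equal(tt3$optimal_week, 2)

  expect_error(fit_time_trend(tibble::tibble(week = c(2, 13),
                                             auc_mean = c(0.6, 0.7))),
               "3 distinct weeks")
})

test_that("per-family trends recover a planted peak week", {
  pw <- planted_week_effect_design(peak_week = 13, amplitude = 1.8,
                                   n_tbi = 150, n_sham = 150,
                                   n_experiments = 4)
  g <- generate_cohort(pw$design, pw$effects, seed = 14)
  tr <- auc_time_trends(g$cohort, B = 15, seed = 14)
  expect_true("MWM:H" %in% names(tr$trends))
  mwm <- tr$trends[["MWM:H"]]
  expect_lt(mwm$coefficients[["c"]], 0)  # concave
  expect_gt(mwm$optimal_week, 6)
  expect_lt(mwm$optimal_week, 22)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(38)
  for (i in 1:5) {
    y <- sample(c(0, 1), 40, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- rnorm(40)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(auc_pairs(s, y), ref)
  }
})
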