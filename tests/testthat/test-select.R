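test_that("best_in_group enumerates subsets and applies the threshold", {
  # 3-member group, fully observed, large n: all 7 subsets evaluated
  d <- make_classif_data(200, p = 3, effect = 1.5, seed = 21)
  co <- cohort_from_matrix(as.matrix(d[, 1:3]), colnames(d)[1:3],
                           groups = d$group)
  res <- best_in_group(co, colnames(d)[1:3], B = 10, seed = 21)
  expect_equal(res$n_candidates, 7L)
  expect_equal(res$n_refused, 0L)
  expect_true(res$qualified)
  expect_true(res$auc_mean - res$auc_sd > 0.75)

  # 1-member group: qualification reduces to its own AUC - SD
  res1 <- best_in_group(co, colnames(d)[1], B = 10, seed = 21)
  expect_equal(res1$n_candidates, 1L)
  expect_equal(res1$qualified, res1$auc_mean - res1$auc_sd > 0.75)

  # null effect: not qualified
  dn <- make_classif_data(200, p = 2, effect = 0, seed = 22)
  con <- cohort_from_matrix(as.matrix(dn[, 1:2]), colnames(dn)[1:2],
                            groups = dn$group)
  resn <- best_in_group(con, colnames(dn)[1:2], B = 10, seed = 22)
  expect_false(resn$qualified)

  # all subsets refused: reported unqualified with the refusal reason
  tiny <- make_classif_data(12, p = 2, seed = 23)
  cot <- cohort_from_matrix(as.matrix(tiny[, 1:2]), colnames(tiny)[1:2],
                            groups = tiny$group)
  rest <- best_in_group(cot, colnames(tiny)[1:2], B = 10, seed = 23)
  expect_false(rest$qualified)
  expect_match(rest$refusal_reason, "not run")
})

test_that("best_in_group equals exhaustive enumeration on small groups", {
  # the winner must be the argmax over an independent full enumeration with
  # the same per-subset seeds
  d <- make_classif_data(150, p = 4, effect = 1, seed = 24)
  codes <- colnames(d)[1:4]
  co <- cohort_from_matrix(as.matrix(d[, 1:4]), codes, groups = d$group)
  res <- best_in_group(co, codes, B = 8, seed = 24)
  all_aucs <- c()
  for (s in 1:4) for (cmb in utils::combn(codes, s, simplify = FALSE)) {
    r <- bootstrap_auc(cohort_table(co, cmb), cmb, B = 8,
                       seed = batterysel:::.derive_seed(24, paste(cmb, collapse = "|")))
    all_aucs <- c(all_aucs, setNames(r$auc_mean, paste(cmb, collapse = "|")))
  }
  expect_equal(res$auc_mean, max(all_aucs))
  expect_equal(paste(res$variables[[1]], collapse = "|"),
               names(all_aucs)[which.max(all_aucs)])
})

test_that("maximum_model equals brute-force enumeration on random masks", {
  set.seed(25)
  codes <- c("MWM:H1:W2", "MWM:H2:W2", "MWM:V1:W2", "EPM:O:W2",
             "OF:C:C:W2", "OF:C:N:W2", "Rota:D2:W2", "FST:D1:W2")
  for (rep in 1:12) {
    n <- sample(c(60, 90, 140), 1)
    vals <- matrix(rnorm(n * length(codes)), n)
    for (j in seq_along(codes)) {
      vals[runif(n) > runif(1, 0.25, 0.95), j] <- NA
    }
    co <- cohort_from_matrix(vals, codes)
    mm <- tryCatch(maximum_model(co, codes), error = function(e) character(0))
    expect_identical(sort(mm), sort(brute_maximum_model(co, codes)),
                     label = paste("mask", rep))
  }
  # fully observed with ample n: the maximum model is all candidates
  full <- cohort_from_matrix(matrix(rnorm(200 * 4), 200),
                             codes[1:4])
  expect_setequal(maximum_model(full, codes[1:4]), codes[1:4])
  # two disjointly measured blocks: confined to the larger feasible block
  vals <- matrix(NA_real_, 120, 4)
  vals[1:80, 1:2] <- rnorm(160)
  vals[81:120, 3:4] <- rnorm(80)
  co2 <- cohort_from_matrix(vals, codes[1:4])
  expect_setequal(maximum_model(co2, codes[1:4]), codes[1:2])
  # infeasible: everything too sparse
  sparse <- cohort_from_matrix(rbind(matrix(rnorm(20), 5, 4),
                                     matrix(NA_real_, 100, 4)), codes[1:4])
  expect_error(maximum_model(sparse, codes[1:4]), "no nonempty subset")
})

test_that("the cascade is deterministic and respects the null threshold", {
  pw <- planted_week_effect_design(amplitude = 0, n_tbi = 60, n_sham = 60,
                                   n_experiments = 2, weeks = c(2L, 13L))
  g <- generate_cohort(pw$design, pw$effects, seed = 26)
  r1 <- run_cascade(g$cohort, B = 10, seed = 26)
  r2 <- run_cascade(g$cohort, B = 10, seed = 26)
  expect_identical(r1$level3, r2$level3)
  expect_identical(r1$level1, r2$level1)
  # a null cohort should qualify nothing at level 3
  expect_equal(sum(r1$level3$qualified), 0L)
  expect_equal(NROW(r1$level2), 0L)
})

test_that("raising the threshold never adds qualified models", {
  pw <- planted_week_effect_design(amplitude = 1.5, n_tbi = 120, n_sham = 120,
                                   n_experiments = 4)
  g <- generate_cohort(pw$design, pw$effects, seed = 27)
  lo <- run_cascade(g$cohort, B = 10, threshold = 0.70, seed = 27)
  hi <- run_cascade(g$cohort, B = 10, threshold = 0.85, seed = 27)
  expect_lte(sum(hi$level3$qualified), sum(lo$level3$qualified))
  # qualified sets are nested (same seeds, same AUCs, stricter cut)
  key <- function(r) paste0(r$level3$level3, "@", r$level3$week)[r$level3$qualified]
  expect_true(all(key(hi) %in% key(lo)))
})

test_that("with complete data the level-2 maximum model pools all qualified variables", {
  d <- make_classif_data(400, p = 4, effect = 2, seed = 28)
  codes <- colnames(d)[1:4]  # two level-3 groups: MWM:H1..4 all at W2
  co <- cohort_from_matrix(as.matrix(d[, 1:4]), codes, groups = d$group)
  rep <- run_cascade(co, B = 10, seed = 28)
  qual_vars <- sort(unique(unlist(rep$level3$variables[rep$level3$qualified])))
  expect_gt(length(qual_vars), 0L)
  expect_setequal(rep$level2$maximum_model[[1]], qual_vars)
})

test_that("the cascade recovers a planted peak-week variable", {
  pw <- planted_week_effect_design(peak_week = 13, amplitude = 1.5,
                                   n_tbi = 200, n_sham = 200)
  g <- generate_cohort(pw$design, pw$effects, seed = 29)
  rep <- run_cascade(g$cohort, B = 25, seed = 29)
  cog <- rep$level1[rep$level1$key == "cognitive", ]
  expect_equal(nrow(cog), 1L)
  expect_true(any(grepl(":W13$", cog$variables[[1]])))
  # motor carried no effect: nothing qualifies there
  expect_false("motor" %in% rep$level1$key)
})
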