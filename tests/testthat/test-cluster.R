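test_that("the adjusted Rand index matches hand-computed contingency values", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)  # renaming
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  # hand evaluation for a 6-item case: contingency {{2,1},{0,3}}
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 2, 2, 2)
  # sum_ij C(nij,2) = 1 + 0 + 0 + 3 = 4; sum_a = 3 + 3 = 6; sum_b = 1 + 6 = 7
  # exp = 42/15 = 2.8; max = 6.5 -> ARI = (4 - 2.8)/(6.5 - 2.8)
  expect_equal(adjusted_rand_index(a, b), (4 - 2.8) / (6.5 - 2.8))
  expect_error(adjusted_rand_index(1:3, 1:4), "differ in length")
})

test_that("ARI is symmetric, renaming-invariant, and 0 in expectation at chance", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
    relab <- c(9, 7, 8, 5)[b]
    expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(a, relab))
  }
  labels <- rep(c(0, 1), 500)
  aris <- vapply(1:200, function(i) {
    adjusted_rand_index(sample(c(0, 1), 1000, replace = TRUE), labels)
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.02)
})

test_that("k-means recovers separated structure deterministically", {
  # two point-masses: exact recovery
  x <- rbind(matrix(0, 10, 2), matrix(5, 12, 2))
  cl <- kmeans_partition(x, k = 2, seed = 1)
  expect_equal(length(unique(cl[1:10])), 1L)
  expect_equal(length(unique(cl[11:22])), 1L)
  expect_false(cl[1] == cl[22])

  # identical rows always share a label
  set.seed(32)
  base <- matrix(rnorm(30), 10, 3)
  dup <- rbind(base, base)
  cl2 <- kmeans_partition(dup, k = 3, seed = 2)
  expect_equal(cl2[1:10], cl2[11:20])

  # WCSS no worse than random assignments
  y <- matrix(rnorm(200), 50, 4)
  cl3 <- kmeans_partition(y, k = 2, seed = 3)
  wcss <- function(x, cl) {
    sum(vapply(unique(cl), function(g) {
      xg <- x[cl == g, , drop = FALSE]
      sum(sweep(xg, 2, colMeans(xg))^2)
    }, numeric(1)))
  }
  w_fit <- wcss(y, cl3)
  set.seed(33)
  for (i in 1:100) {
    expect_lte(w_fit, wcss(y, sample(1:2, 50, replace = TRUE)))
  }

  expect_error(kmeans_partition(y[1:1, , drop = FALSE], k = 2), "fewer rows")
  # determinism
  expect_identical(kmeans_partition(y, k = 2, seed = 7),
                   kmeans_partition(y, k = 2, seed = 7))
})

test_that("the combination scan enumerates the right subsets", {
  counts <- scan_combination_counts(15)
  expect_equal(counts$n_combinations[counts$size == 7], 6435)
  expect_equal(counts$n_combinations[counts$size == 8], 6435)
  expect_equal(counts$n_combinations[counts$size == 15], 1)
  expect_equal(max(counts$total), 32767)

  # full enumeration on a 4-code core: per-size counts match binomials
  d <- make_classif_data(60, p = 4, effect = 1, seed = 34)
  co <- cohort_from_matrix(as.matrix(d[, 1:4]), colnames(d)[1:4],
                           groups = d$group)
  sc <- combination_scan(co, colnames(d)[1:4], seed = 34)
  expect_equal(sc$size_summary$n_evaluated, choose(4, 1:4))
  expect_equal(nrow(sc$results), 2^4 - 1)
  # every evaluated subset is distinct
  keys <- vapply(sc$results$codes, paste, character(1), collapse = "|")
  expect_false(anyDuplicated(keys) > 0)
})

test_that("planted separation raises ARI with combination size", {
  d <- make_classif_data(240, p = 6, effect = 1.4, seed = 35)
  co <- cohort_from_matrix(as.matrix(d[, 1:6]), colnames(d)[1:6],
                           groups = d$group)
  sc <- combination_scan(co, colnames(d)[1:6], seed = 35)
  med <- setNames(sc$size_summary$ari_median, sc$size_summary$size)
  expect_gt(med[["6"]], med[["1"]])
})

test_that("a null cohort scans to chance-level ARI", {
  d <- make_classif_data(200, p = 5, effect = 0, seed = 36)
  co <- cohort_from_matrix(as.matrix(d[, 1:5]), colnames(d)[1:5],
                           groups = d$group)
  sc <- combination_scan(co, colnames(d)[1:5], seed = 36)
  expect_lt(abs(mean(sc$results$ari)), 0.03)
})

test_that("ARI agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(37)
  for (i in 1:10) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:2, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
})
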