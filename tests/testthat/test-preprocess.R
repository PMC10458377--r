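test_that("scaling yields unit-variance columns and logs 5-SD outliers", {
  set.seed(11)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, sprintf("c%d", 1:4)))
  st <- scale_and_trim(x)
  expect_equal(unname(apply(st$values, 2, sd)), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(colMeans(st$values)), rep(0, 4), tolerance = 1e-9)
  expect_equal(nrow(st$removed), 0L)

  # one mouse at z = 6 on one column is removed whole and logged
  x2 <- x
  x2[7, 2] <- mean(x[, 2]) + 10 * sd(x[, 2])
  rownames(x2) <- sprintf("m%02d", 1:50)
  st2 <- scale_and_trim(x2)
  expect_equal(nrow(st2$values), 49L)
  expect_equal(st2$removed$row, "m07")
  expect_equal(st2$removed$code, "c2")
  expect_gt(st2$removed$z, 5)

  # single pass: idempotent on its own output
  st3 <- scale_and_trim(st2$values)
  expect_equal(nrow(st3$values), nrow(st2$values))
  expect_equal(nrow(st3$removed), 0L)

  # zero-variance column is an error naming the code
  x3 <- x
  x3[, 3] <- 1
  expect_error(scale_and_trim(x3), "zero-variance.*c3")
})

test_that("PCA reconstructs the scaled matrix and orders variance", {
  set.seed(12)
  x <- matrix(rnorm(300), 60, 5)
  st <- scale_and_trim(x)
  p <- pca_outcomes(st)
  expect_equal(p$scores %*% t(p$loadings), unclass(st$values),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(sum(p$var_explained), 1, tolerance = 1e-9)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_equal(crossprod(p$loadings), diag(5), ignore_attr = TRUE,
               tolerance = 1e-9)
  # sign convention: largest-magnitude loading entry positive
  for (j in 1:5) {
    v <- p$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("PCA variance matches structure: collinearity and isotropy", {
  # two perfectly correlated columns -> PC1 explains everything
  z <- rnorm(40)
  p <- pca_outcomes(scale_and_trim(cbind(a = z, b = 2 * z + 3)))
  expect_equal(p$var_explained[[1]], 1, tolerance = 1e-9)

  # isotropic 2-D Gaussian -> fractions ~(0.5, 0.5)
  set.seed(13)
  p2 <- pca_outcomes(matrix(rnorm(20000), 10000, 2))
  expect_equal(p2$var_explained, c(0.5, 0.5), tolerance = 0.02)
})

test_that("explained variance is invariant to row permutation", {
  set.seed(14)
  x <- matrix(rnorm(240), 40, 6)
  p1 <- pca_outcomes(scale_and_trim(x))
  p2 <- pca_outcomes(scale_and_trim(x[sample(40), ]))
  expect_equal(p1$var_explained, p2$var_explained, tolerance = 1e-12)
})

test_that("sign-flipped outcome blocks mirror their PC1 correlations", {
  # half the codes flipped in sign: same magnitude pattern on PC1, opposite
  # signs across blocks (a directionality component)
  set.seed(15)
  latent <- rnorm(300)
  x <- sapply(1:6, function(j) latent + rnorm(300, sd = 0.6))
  x[, 4:6] <- -x[, 4:6]
  p <- pca_outcomes(scale_and_trim(x))
  c1 <- p$correlations[, 1]
  expect_true(all(abs(c1) > 0.5))
  expect_true(all(sign(c1[1:3]) == sign(c1[[1]])))
  expect_true(all(sign(c1[4:6]) == -sign(c1[[1]])))
})

test_that("group summaries recover planted displacement and spread", {
  set.seed(16)
  scores <- rbind(cbind(rnorm(200), rnorm(200)),
                  cbind(rnorm(200) + 10, rnorm(200)))
  colnames(scores) <- c("PC1", "PC2")
  grouping <- rep(c("a", "b"), each = 200)
  gs <- group_summary(scores, grouping)
  expect_equal(nrow(gs), 2L)
  d <- diff(gs$mean_x)
  expect_equal(abs(d), 10, tolerance = 0.5)
  expect_equal(gs$axis_major, c(1, 1), tolerance = 0.25)  # near-circular
  # a singleton group is skipped with a warning
  expect_warning(
    gs2 <- group_summary(scores[1:5, ], c("a", "a", "a", "a", "solo")),
    "single mouse")
  expect_equal(gs2$group, "a")
  # one group -> centroid at the global mean
  gs3 <- group_summary(scores, rep("all", 400))
  expect_equal(gs3$mean_x, mean(scores[, 1]))
})

test_that("complete-linkage ordering matches hand-computed merges", {
  # 4-row toy with known complete-linkage structure
  m <- rbind(a = c(0, 0), b = c(0, 0.1), c = c(4, 0), d = c(4.2, 0))
  res <- correlation_ordering(m)
  hc <- res$hclust
  expect_true(all(diff(hc$height) >= -1e-12))
  # hand computation: merges at 0.1 (a,b), 0.2 (c,d), then max pairwise
  # distance between the two pairs
  expect_equal(sort(hc$height)[1:2], c(0.1, 0.2), tolerance = 1e-9)
  expect_equal(max(hc$height), sqrt(4.2^2 + 0.1^2), tolerance = 1e-9)
  expect_setequal(res$order, 1:4)
  # identical rows merge at height 0 and sit adjacent
  m2 <- rbind(x = c(1, 2), y = c(1, 2), z = c(5, 5))
  res2 <- correlation_ordering(m2)
  expect_equal(min(res2$hclust$height), 0)
  pos <- match(c("x", "y"), res2$labels)
  expect_equal(abs(diff(pos)), 1L)
})

test_that("experiment blocks with extra anesthesia separate in PC space", {
  # planted anesthesia effect: a 7-procedure block against 1-procedure blocks
  battery <- sprintf("MWM:H%d:W2", 1:4)
  blocks <- tibble::tibble(
    experiment_id = c("E1", "E2", "E3"),
    n_tbi = 0, n_sham = c(40, 40, 40), drop_height_in = 0,
    n_hits = c(1L, 1L, 7L), schedule = c("1x", "1x", "7_in_9_days"),
    age_weeks = 8L, treatment = "none", treatment_route = "none",
    battery = list(battery, battery, battery))
  eff <- effect_spec(level3 = "MWM:H", week = 2L, baseline = 40, sd = 6,
                     anesthesia_slope = 3)
  g <- generate_cohort(design_from_blocks(blocks), eff, seed = 21)
  wide <- cohort_table(g$cohort, battery)
  m <- as.matrix(wide[, battery])
  rownames(m) <- wide$mouse_id
  st <- scale_and_trim(m)
  p <- pca_outcomes(st)
  keep <- rownames(st$values)
  hits <- wide$n_hits[match(keep, wide$mouse_id)]
  gs <- group_summary(p$scores, ifelse(hits == 7, "seven", "fewer"))
  pooled <- sqrt(mean(c(gs$var_x, gs$var_y)))
  sep <- max(abs(diff(gs$mean_x)), abs(diff(gs$mean_y)))
  expect_gt(sep, 2 * pooled)
})
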