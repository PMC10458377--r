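# Bootstrapped and cross-validated AUC of logistic TBI-vs-sham classifiers.
#
# Models are fitted by binomial IRLS on the behavioral predictors plus the
# number-of-procedures adjustment covariate, guarded by the rule that at least
# 10 mice are required per predictor (behavioral predictors plus the
# adjustment covariate; the intercept is not counted). Performance is the AUC
# on held-out mice: out-of-bag mice for bootstrap resamples, held-out folds
# for cross-validation.

#' Area under the ROC curve by pair counting
#'
#' The probability that a randomly chosen positive (TBI) score exceeds a
#' randomly chosen negative (sham) score, with ties counted 1/2 — the
#' Mann-Whitney form of the AUC, computed from midranks. Scores below 0.5 are
#' reported as-is, never flipped.
#'
#' @param scores Numeric vector of classifier scores (any strictly increasing
#'   transform gives the same AUC).
#' @param labels Binary labels (logical, 0/1, or `"TBI"`/`"sham"`); the
#'   positive class is `TRUE`/`1`/`"TBI"`.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_pairs(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
auc_pairs <- function(scores, labels) {
  y <- .as_binary(labels)
  stopifnot(length(scores) == length(y))
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

.as_binary <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    stopifnot(all(labels %in% c("TBI", "sham")))
    as.integer(labels == "TBI")
  } else {
    y <- as.integer(as.logical(labels))
    stopifnot(all(y %in% c(0L, 1L)))
    y
  }
}

# 10-mice-per-variable guard. p = behavioral predictors + adjustment
# covariates (intercept excluded).
.check_guard <- function(n, p, min_per_variable = 10) {
  if (n < min_per_variable * p) {
    stop("model not run: ", n, " mice for ", p, " predictors (needs >= ",
         min_per_variable * p, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit a guarded logistic classifier
#'
#' Maximum-likelihood logistic regression by iteratively reweighted least
#' squares (convergence tolerance 1e-8 on the deviance, at most 50
#' iterations; under complete separation the iteration cap stops the fit, and
#' the score ranking — hence the AUC — is unaffected). Refuses to run when
#' there are fewer than `min_per_variable` mice per predictor.
#'
#' @param x Numeric predictor matrix (behavioral variables plus any
#'   adjustment covariates; no intercept column).
#' @param y Binary labels (see [auc_pairs()]).
#' @param min_per_variable Sample-size guard (default 10 mice per predictor).
#' @return A `logistic_fit`: list with `coefficients` (incl. intercept) and
#'   `predict(newx)` returning linear-predictor scores.
#' @export
fit_logistic <- function(x, y, min_per_variable = 10) {
  x <- as.matrix(x)
  y <- .as_binary(y)
  stopifnot(nrow(x) == length(y))
  if (anyNA(x)) stop("predictor matrix contains missing values", call. = FALSE)
  .check_guard(nrow(x), ncol(x), min_per_variable)
  xm <- cbind(`(Intercept)` = 1, x)
  fit <- suppressWarnings(stats::glm.fit(
    xm, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 50)
  ))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0  # aliased columns contribute nothing to the score
  structure(
    list(coefficients = beta,
         predict = function(newx) {
           drop(cbind(1, as.matrix(newx)) %*% beta)
         }),
    class = "logistic_fit"
  )
}

# Assemble the design matrix for a variable set from a wide data frame.
.model_frame <- function(data, variables, adjust) {
  cols <- c(variables, adjust)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L) {
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  list(x = as.matrix(data[keep, cols, drop = FALSE]),
       y = .as_binary(data$group[keep]),
       keep = keep)
}

.model_result <- function(variables, adjust, y, aucs, method, requested) {
  tibble::tibble(
    variables = list(sort(variables)),
    adjustment = list(adjust),
    n_total = length(y), n_tbi = sum(y == 1L), n_sham = sum(y == 0L),
    auc_mean = mean(aucs), auc_sd = stats::sd(aucs),
    method = method, iterations_used = length(aucs),
    iterations_requested = requested
  )
}

#' Bootstrapped out-of-bag AUC of an adjusted logistic model
#'
#' Repeatedly resamples mice with replacement, fits the guarded logistic
#' model on each resample, scores the out-of-bag mice, and records the AUC on
#' them; reports the mean and SD over iterations. Iterations whose resample
#' or out-of-bag set contains a single class are redrawn (up to 10 times
#' each, then skipped and counted in `iterations_used`).
#'
#' @param data A data frame with a `group` column (`"TBI"`/`"sham"` or 0/1)
#'   and numeric predictor columns; rows with missing predictor values are
#'   dropped (complete-case analysis).
#' @param variables Character vector of behavioral predictor columns.
#' @param adjust Adjustment covariate columns (default `"n_hits"`, the number
#'   of TBI/sham procedures, as a numeric count). Use `NULL` for none.
#' @param B Number of bootstrap iterations (default 25).
#' @param seed Integer seed; fixed seed gives identical results.
#' @param min_per_variable Sample-size guard (default 10).
#' @return A one-row `model_result` tibble: `variables`, `adjustment`,
#'   `n_total`, `n_tbi`, `n_sham`, `auc_mean`, `auc_sd`, `method`,
#'   `iterations_used`, `iterations_requested`.
#' @export
bootstrap_auc <- function(data, variables, adjust = "n_hits", B = 25, seed = 1,
                          min_per_variable = 10) {
  mf <- .model_frame(data, variables, adjust)
  x <- mf$x
  y <- mf$y
  n <- nrow(x)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  .check_guard(n, ncol(x), min_per_variable)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(.derive_seed(seed, "bootstrap_auc"), kind = "Mersenne-Twister")
  aucs <- numeric(0)
  for (b in seq_len(B)) {
    auc_b <- NA_real_
    for (try in seq_len(10L)) {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      if (length(unique(y[idx])) < 2L || length(unique(y[oob])) < 2L) next
      fit <- fit_logistic(x[idx, , drop = FALSE], y[idx],
                          min_per_variable = 0)
      auc_b <- auc_pairs(fit$predict(x[oob, , drop = FALSE]), y[oob])
      break
    }
    if (!is.na(auc_b)) aucs <- c(aucs, auc_b)
  }
  if (length(aucs) == 0L) stop("all bootstrap iterations were invalid", call. = FALSE)
  .model_result(variables, adjust, y, aucs, "boot25", B)
}

#' Cross-validated AUC of an adjusted logistic model
#'
#' Stratified k-fold cross-validation: the model is fitted on k-1 folds and
#' the AUC computed on the held-out fold; the mean and SD over folds are
#' reported.
#'
#' @inheritParams bootstrap_auc
#' @param folds Number of folds (default 10). Each class must have at least
#'   `folds` mice.
#' @return A one-row `model_result` tibble (`method = "cv10"`).
#' @export
cv_auc <- function(data, variables, adjust = "n_hits", folds = 10, seed = 1,
                   min_per_variable = 10) {
  mf <- .model_frame(data, variables, adjust)
  x <- mf$x
  y <- mf$y
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  if (min(sum(y == 1L), sum(y == 0L)) < folds) {
    stop("fewer than ", folds, " mice in a class; folds infeasible", call. = FALSE)
  }
  .check_guard(nrow(x), ncol(x), min_per_variable)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(.derive_seed(seed, "cv_auc"), kind = "Mersenne-Twister")
  fold_of <- integer(length(y))
  for (cls in c(0L, 1L)) {
    i <- which(y == cls)
    fold_of[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  aucs <- vapply(seq_len(folds), function(k) {
    test <- fold_of == k
    fit <- fit_logistic(x[!test, , drop = FALSE], y[!test], min_per_variable = 0)
    auc_pairs(fit$predict(x[test, , drop = FALSE]), y[test])
  }, numeric(1))
  .model_result(variables, adjust, y, aucs, "cv10", folds)
}

#' Quadratic time trend of discrimination performance
#'
#' Fits `auc ~ a + b*week + c*week^2` by ordinary least squares to the
#' per-week AUC means of one parameter family. The optimal week is the vertex
#' `-b/(2c)` when the parabola opens downward and the vertex lies inside the
#' observed week range; otherwise the observed boundary week with the highest
#' fitted value (earliest such week on ties).
#'
#' @param points A data frame with columns `week` and `auc_mean` (optionally
#'   `auc_sd`, `n`), at least 3 distinct weeks.
#' @param family Optional family label carried into the result.
#' @return A `time_trend`: list with `family`, `points`, `coefficients`
#'   (a, b, c) and `optimal_week`.
#' @export
fit_time_trend <- function(points, family = NA_character_) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("week", "auc_mean") %in% names(points)))
  if (length(unique(points$week)) < 3L) {
    stop("time trend requires results at >= 3 distinct weeks", call. = FALSE)
  }
  w <- points$week
  fit <- stats::lm.fit(cbind(1, w, w^2), points$auc_mean)
  cf <- fit$coefficients
  names(cf) <- c("a", "b", "c")
  cf[is.na(cf)] <- 0
  rng <- range(w)
  vertex <- if (cf[["c"]] < 0) -cf[["b"]] / (2 * cf[["c"]]) else NA_real_
  if (!is.na(vertex) && vertex >= rng[[1]] && vertex <= rng[[2]]) {
    opt <- vertex
  } else {
    fitted_at <- function(x) cf[["a"]] + cf[["b"]] * x + cf[["c"]] * x^2
    ends <- sort(unique(rng))
    opt <- ends[[which.max(vapply(ends, fitted_at, numeric(1)))]]
  }
  structure(
    list(family = family, points = points, coefficients = cf,
         optimal_week = unname(opt)),
    class = "time_trend"
  )
}

#' Per-family AUC time trends across testing weeks
#'
#' Runs [bootstrap_auc()] for each (level-3 family, week) cell with enough
#' mice, using all members of the family at that week as one model, and fits
#' a quadratic trend per family with at least 3 measured weeks.
#'
#' @param cohort A `tbi_cohort`.
#' @param codes Candidate codes (default: non-severity, non-redundant measured
#'   codes).
#' @param B,seed,min_per_variable Passed to [bootstrap_auc()].
#' @return A list with `points` (tibble of per-(family, week) model results)
#'   and `trends` (named list of `time_trend` objects).
#' @export
auc_time_trends <- function(cohort, codes = NULL, B = 25, seed = 1,
                            min_per_variable = 10) {
  stopifnot(inherits(cohort, "tbi_cohort"))
  if (is.null(codes)) {
    codes <- intersect(behavioral_codes(cohort$registry),
                       unique(cohort$measurements$outcome_code))
  }
  groups <- group_level3(codes, cohort$registry)
  pts <- list()
  for (i in seq_len(nrow(groups))) {
    vars <- groups$codes[[i]]
    data <- cohort_table(complete_case_subset(cohort, vars), vars)
    res <- tryCatch(
      bootstrap_auc(data, vars, B = B,
                    seed = .derive_seed(seed, paste0("trend:", groups$level3[[i]],
                                                     ":", groups$week[[i]])),
                    min_per_variable = min_per_variable),
      error = function(e) NULL
    )
    if (is.null(res)) next
    pts[[length(pts) + 1L]] <- dplyr::mutate(
      res, level3 = groups$level3[[i]], week = groups$week[[i]], .before = 1)
  }
  points <- dplyr::bind_rows(pts)
  trends <- list()
  if (nrow(points) > 0L) {
    for (fam in unique(points$level3)) {
      sub <- points[points$level3 == fam, ]
      if (length(unique(sub$week)) >= 3L) {
        trends[[fam]] <- fit_time_trend(sub[, c("week", "auc_mean", "auc_sd",
                                                "n_total")], family = fam)
      }
    }
  }
  list(points = points, trends = trends)
}
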