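# Hierarchical best-model selection.
#
# Level 3: within each (parameter family, week) group, every subset of the
# group's variables that passes the sample-size guard is scored by
# bootstrapped AUC; the best subset qualifies when AUC mean minus one SD
# exceeds the threshold (strictly). Level 2: per test, the variables of the
# qualified level-3 best models are pooled, the largest jointly-complete
# subset under the guard (the "maximum model") is found, and the best subset
# within it is scored the same way. Level 1 repeats this per behavioral
# category. Ties anywhere are broken deterministically: fewer variables, then
# more complete-case mice, then canonical code order.

# All nonempty subsets of a code vector, smallest first, canonical order
# within a size. Guarded by a size cap: subset search is exhaustive.
.subsets <- function(codes, max_size = length(codes)) {
  codes <- sort(codes)
  out <- list()
  for (s in seq_len(min(length(codes), max_size))) {
    cmb <- utils::combn(codes, s, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

# Deterministic comparison of candidate models: higher AUC mean, then fewer
# variables, then larger n, then canonical code order.
.better_model <- function(a, b) {
  if (is.null(b)) return(TRUE)
  if (a$auc_mean != b$auc_mean) return(a$auc_mean > b$auc_mean)
  la <- length(a$variables[[1]]); lb <- length(b$variables[[1]])
  if (la != lb) return(la < lb)
  if (a$n_total != b$n_total) return(a$n_total > b$n_total)
  paste(a$variables[[1]], collapse = ",") < paste(b$variables[[1]], collapse = ",")
}

#' Best qualified model within one level-3 group
#'
#' Scores every nonempty subset of the group's member codes that passes the
#' sample-size guard by [bootstrap_auc()] on its own complete cases, records
#' the best subset under the deterministic tie rules, and marks it qualified
#' when `auc_mean - auc_sd > threshold` (strict).
#'
#' @param cohort A `tbi_cohort`.
#' @param codes Member codes of the group (a level-3 family at one week).
#' @param B Bootstrap iterations (default 25).
#' @param seed Integer seed.
#' @param threshold Qualification threshold on AUC mean minus SD (default 0.75).
#' @param adjust Adjustment covariates (default `"n_hits"`).
#' @param min_per_variable Sample-size guard (default 10).
#' @param max_size Cap on subset size for the exhaustive search (default 20).
#' @return A one-row tibble: the best `model_result` columns plus `qualified`,
#'   `n_candidates` (subsets evaluated), `n_refused` (subsets refused by the
#'   guard), and `refusal_reason` when nothing could be run.
#' @export
best_in_group <- function(cohort, codes, B = 25, seed = 1, threshold = 0.75,
                          adjust = "n_hits", min_per_variable = 10,
                          max_size = 20) {
  stopifnot(inherits(cohort, "tbi_cohort"), length(codes) >= 1L)
  subsets <- .subsets(codes, max_size)
  best <- NULL
  n_eval <- 0L
  n_refused <- 0L
  last_refusal <- NA_character_
  for (i in seq_along(subsets)) {
    vars <- subsets[[i]]
    sub <- complete_case_subset(cohort, vars)
    data <- cohort_table(sub, vars)
    res <- tryCatch(
      bootstrap_auc(data, vars, adjust = adjust, B = B,
                    seed = .derive_seed(seed, paste(vars, collapse = "|")),
                    min_per_variable = min_per_variable),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      n_refused <- n_refused + 1L
      last_refusal <- conditionMessage(res)
      next
    }
    n_eval <- n_eval + 1L
    if (.better_model(res, best)) best <- res
  }
  if (is.null(best)) {
    return(tibble::tibble(
      variables = list(character(0)), adjustment = list(adjust),
      n_total = 0L, n_tbi = 0L, n_sham = 0L,
      auc_mean = NA_real_, auc_sd = NA_real_, method = "boot25",
      iterations_used = 0L, iterations_requested = B,
      qualified = FALSE, n_candidates = n_eval, n_refused = n_refused,
      refusal_reason = last_refusal
    ))
  }
  dplyr::mutate(best,
                qualified = .data$auc_mean - .data$auc_sd > threshold,
                n_candidates = n_eval, n_refused = n_refused,
                refusal_reason = NA_character_)
}

#' Largest variable subset with enough jointly complete cases
#'
#' Finds the subset S of the candidate codes maximizing |S| subject to the
#' sample-size guard: the mice complete on S (and the adjustment covariate)
#' must number at least `min_per_variable * (|S| + n_adjust)`. Exhaustive
#' branch-and-bound search exploiting monotonicity (adding a variable never
#' increases the complete-case count); ties on |S| are broken by larger
#' complete-case n, then canonical code order.
#'
#' @param cohort A `tbi_cohort`.
#' @param candidates Candidate codes (nonempty).
#' @param n_adjust Number of adjustment covariates counted by the guard
#'   (default 1, the number of procedures).
#' @param min_per_variable Guard multiplier (default 10).
#' @param max_size Cap on |S| (default 20).
#' @return Character vector: the maximum model's codes (canonical order).
#'   Errors if no nonempty subset is feasible.
#' @export
maximum_model <- function(cohort, candidates, n_adjust = 1L,
                          min_per_variable = 10, max_size = 20) {
  stopifnot(inherits(cohort, "tbi_cohort"), length(candidates) >= 1L)
  candidates <- sort(unique(candidates))
  p <- length(candidates)
  # availability matrix: mice x candidates
  meas <- dplyr::filter(cohort$measurements, .data$outcome_code %in% candidates)
  ids <- unique(meas$mouse_id)
  avail <- matrix(FALSE, nrow = length(ids), ncol = p,
                  dimnames = list(ids, candidates))
  avail[cbind(match(meas$mouse_id, ids), match(meas$outcome_code, candidates))] <- TRUE

  feasible <- function(mask, size) {
    n_cc <- if (size == 0L) nrow(avail) else sum(mask)
    n_cc >= min_per_variable * (size + n_adjust)
  }
  best <- NULL   # list(set = integer indices, n = complete-case count)
  # depth-first over candidate indices in canonical order; prune when even
  # taking all remaining candidates cannot beat the incumbent
  recurse <- function(start, set, mask) {
    size <- length(set)
    n_cc <- if (size == 0L) nrow(avail) else sum(mask)
    if (size > 0L && feasible(mask, size)) {
      if (is.null(best) || size > length(best$set) ||
          (size == length(best$set) && n_cc > best$n)) {
        best <<- list(set = set, n = n_cc)
      }
    }
    if (size >= max_size) return()
    remaining <- p - start + 1L
    if (remaining <= 0L) return()
    if (!is.null(best) && size + remaining < length(best$set)) return()
    # guard bound: with n_cc complete cases now, no superset can exceed
    # floor(n_cc / min_per_variable) - n_adjust variables
    if (n_cc < min_per_variable * (size + 1L + n_adjust)) return()
    for (j in start:p) {
      new_mask <- mask & avail[, j]
      recurse(j + 1L, c(set, j), new_mask)
    }
  }
  recurse(1L, integer(0), rep(TRUE, nrow(avail)))
  if (is.null(best)) {
    stop("no nonempty subset of the candidates satisfies the sample-size guard",
         call. = FALSE)
  }
  candidates[best$set]
}

#' Run the full level 3 -> 2 -> 1 selection cascade
#'
#' Level 3: [best_in_group()] for every (parameter family, week) group of the
#' candidate codes. Level 2: per test, pool the variables of that test's
#' qualified level-3 best models, find the [maximum_model()], and search its
#' subsets for the best bootstrapped model. Level 1: the same per behavioral
#' category (cognitive, anxiety/depression, motor), pooling qualified level-2
#' best models. All models are adjusted for the number of procedures; a full
#' refusal log is kept, and empty levels are reported as such.
#'
#' @inheritParams best_in_group
#' @param codes Candidate codes (default: measured non-severity,
#'   non-redundant codes).
#' @return A `selection_report`: list with tibbles `level3`, `level2`,
#'   `level1` and the `threshold`, `seed`, `B` used.
#' @export
run_cascade <- function(cohort, codes = NULL, B = 25, threshold = 0.75,
                        seed = 1, adjust = "n_hits", min_per_variable = 10,
                        max_size = 20) {
  stopifnot(inherits(cohort, "tbi_cohort"))
  if (is.null(codes)) {
    codes <- intersect(behavioral_codes(cohort$registry),
                       unique(cohort$measurements$outcome_code))
  }
  groups <- group_level3(codes, cohort$registry)

  l3 <- list()
  for (i in seq_len(nrow(groups))) {
    res <- best_in_group(
      cohort, groups$codes[[i]], B = B,
      seed = .derive_seed(seed, paste0("L3:", groups$level3[[i]], ":W", groups$week[[i]])),
      threshold = threshold, adjust = adjust,
      min_per_variable = min_per_variable, max_size = max_size)
    l3[[i]] <- dplyr::mutate(res,
                             level3 = groups$level3[[i]], week = groups$week[[i]],
                             level2 = groups$level2[[i]], level1 = groups$level1[[i]],
                             .before = 1)
  }
  level3 <- dplyr::bind_rows(l3)

  run_pooled <- function(pool_tbl, key_col, tag) {
    out <- list()
    for (key in unique(pool_tbl[[key_col]])) {
      vars <- sort(unique(unlist(
        pool_tbl$variables[pool_tbl[[key_col]] == key & pool_tbl$qualified])))
      if (length(vars) == 0L) next
      maxm <- tryCatch(
        maximum_model(cohort, vars, n_adjust = length(adjust),
                      min_per_variable = min_per_variable, max_size = max_size),
        error = function(e) NULL
      )
      if (is.null(maxm)) {
        out[[key]] <- tibble::tibble(
          key = key, maximum_model = list(character(0)),
          variables = list(character(0)), adjustment = list(adjust),
          n_total = 0L, n_tbi = 0L, n_sham = 0L,
          auc_mean = NA_real_, auc_sd = NA_real_, method = "boot25",
          iterations_used = 0L, iterations_requested = B,
          qualified = FALSE, n_candidates = 0L, n_refused = 0L,
          refusal_reason = "no feasible subset under the sample-size guard")
        next
      }
      res <- best_in_group(cohort, maxm, B = B,
                           seed = .derive_seed(seed, paste0(tag, ":", key)),
                           threshold = threshold, adjust = adjust,
                           min_per_variable = min_per_variable,
                           max_size = max_size)
      out[[key]] <- dplyr::mutate(res, key = key, maximum_model = list(maxm),
                                  .before = 1)
    }
    dplyr::bind_rows(out)
  }

  level2 <- run_pooled(level3, "level2", "L2")
  if (nrow(level2) > 0L) {
    lvl1_of <- cohort$registry$level1[match(
      vapply(level2$variables, function(v) if (length(v)) v[[1]] else NA_character_,
             character(1)),
      cohort$registry$code)]
    level2$level1 <- lvl1_of
  }
  level1 <- if (nrow(level2) > 0L) run_pooled(level2, "level1", "L1") else
    tibble::tibble()

  structure(
    list(level3 = level3, level2 = level2, level1 = level1,
         threshold = threshold, seed = seed, B = B),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report> threshold ", x$threshold, ", B = ", x$B, "\n", sep = "")
  cat("  level 3: ", nrow(x$level3), " groups, ",
      sum(x$level3$qualified), " qualified\n", sep = "")
  if (nrow(x$level2) > 0L) {
    cat("  level 2: ", nrow(x$level2), " tests, ",
        sum(x$level2$qualified), " qualified\n", sep = "")
  } else cat("  level 2: empty\n")
  if (NROW(x$level1) > 0L) {
    for (i in seq_len(nrow(x$level1))) {
      cat("  level 1 [", x$level1$key[[i]], "]: ",
          paste(x$level1$variables[[i]], collapse = " + "),
          " (AUC ", sprintf("%.3f +/- %.3f", x$level1$auc_mean[[i]],
                            x$level1$auc_sd[[i]]),
          ", n = ", x$level1$n_total[[i]], ")\n", sep = "")
    }
  } else cat("  level 1: empty\n")
  invisible(x)
}
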