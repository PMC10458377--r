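# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a selection report
#'
#' One row per evaluated model across all three levels, with list-columns
#' flattened to `|`-separated code strings.
#'
#' @param x A `selection_report` from [run_cascade()].
#' @param ... Ignored.
#' @return A tibble.
#' @method tidy selection_report
#' @export
tidy.selection_report <- function(x, ...) {
  add_level <- function(tbl, level) {
    if (NROW(tbl) == 0L) return(NULL)
    tbl <- .flatten_codes(tbl)
    tbl$level <- level
    if (!"key" %in% names(tbl)) {
      tbl$key <- if (all(c("level3", "week") %in% names(tbl))) {
        paste0(tbl$level3, "@W", tbl$week)
      } else NA_character_
    }
    tbl[, c("level", "key", "variables", "auc_mean", "auc_sd",
            "n_total", "n_tbi", "n_sham", "qualified")]
  }
  dplyr::bind_rows(add_level(x$level3, 3L), add_level(x$level2, 2L),
                   add_level(x$level1, 1L))
}

#' @rdname tidy.selection_report
#' @method glance selection_report
#' @export
glance.selection_report <- function(x, ...) {
  best <- NULL
  if (NROW(x$level1) > 0L) {
    q <- x$level1[x$level1$qualified %in% TRUE, ]
    pool <- if (nrow(q) > 0L) q else x$level1[!is.na(x$level1$auc_mean), ]
    if (nrow(pool) > 0L) best <- pool[which.max(pool$auc_mean), ]
  }
  tibble::tibble(
    threshold = x$threshold, boot_iterations = x$B,
    n_level3_groups = NROW(x$level3),
    n_level3_qualified = sum(x$level3$qualified %in% TRUE),
    n_level2_qualified = sum(x$level2$qualified %in% TRUE),
    n_level1_qualified = if (NROW(x$level1) > 0L) sum(x$level1$qualified %in% TRUE) else 0L,
    best_category = if (!is.null(best)) best$key else NA_character_,
    best_variables = if (!is.null(best)) paste(best$variables[[1]], collapse = "|") else NA_character_,
    best_auc_mean = if (!is.null(best)) best$auc_mean else NA_real_,
    best_auc_sd = if (!is.null(best)) best$auc_sd else NA_real_
  )
}

#' Tidy a PCA result
#'
#' Loadings in long form (one row per outcome-component pair).
#'
#' @param x An `outcome_pca` from [pca_outcomes()].
#' @param ... Ignored.
#' @return A tibble with `code`, `component`, `loading`, `correlation`.
#' @method tidy outcome_pca
#' @export
tidy.outcome_pca <- function(x, ...) {
  k <- ncol(x$loadings)
  kc <- ncol(x$correlations)
  tibble::tibble(
    code = rep(rownames(x$loadings), k),
    component = rep(seq_len(k), each = nrow(x$loadings)),
    loading = as.vector(x$loadings),
    correlation = as.vector(cbind(x$correlations,
                                  matrix(NA_real_, nrow(x$loadings), k - kc)))
  )
}

#' @rdname tidy.outcome_pca
#' @method glance outcome_pca
#' @export
glance.outcome_pca <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$var_explained),
    var_explained_pc1 = x$var_explained[[1]],
    var_explained_pc2 = if (length(x$var_explained) > 1L) x$var_explained[[2]] else NA_real_,
    var_explained_total4 = sum(x$var_explained[seq_len(min(4L, length(x$var_explained)))])
  )
}

#' Tidy an ARI scan
#'
#' @param x An `ari_scan` from [combination_scan()].
#' @param ... Ignored.
#' @return The per-combination results tibble with codes flattened.
#' @method tidy ari_scan
#' @export
tidy.ari_scan <- function(x, ...) .flatten_codes(x$results)

#' @rdname tidy.ari_scan
#' @method glance ari_scan
#' @export
glance.ari_scan <- function(x, ...) {
  tibble::tibble(
    k = x$k, n_codes = length(x$codes),
    n_combinations_total = sum(choose(length(x$codes), seq_along(x$codes))),
    n_evaluated = nrow(x$results),
    ari_median_overall = stats::median(x$results$ari),
    ari_median_max_size = x$size_summary$ari_median[[which.max(x$size_summary$size)]]
  )
}

#' Tidy an accumulation result
#'
#' @param x An `accumulation_result` from [accumulate_studies()].
#' @param ... Ignored.
#' @return The per-iteration results tibble.
#' @method tidy accumulation_result
#' @export
tidy.accumulation_result <- function(x, ...) x$results

#' @rdname tidy.accumulation_result
#' @method glance accumulation_result
#' @export
glance.accumulation_result <- function(x, ...) {
  last <- x$m_summary[which.max(x$m_summary$m), ]
  tibble::tibble(
    outcome = x$outcome, n_eligible_studies = length(x$eligible),
    max_m = last$m, srmse_median_max_m = last$srmse_median,
    n_skipped = NROW(x$skipped)
  )
}

#' Tidy a time trend
#'
#' @param x A `time_trend` from [fit_time_trend()].
#' @param ... Ignored.
#' @return One row per coefficient.
#' @method tidy time_trend
#' @export
tidy.time_trend <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "week", "week^2"),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.time_trend
#' @method glance time_trend
#' @export
glance.time_trend <- function(x, ...) {
  tibble::tibble(family = x$family, optimal_week = x$optimal_week,
                 n_weeks = length(unique(x$points$week)),
                 curvature = unname(x$coefficients[["c"]]))
}
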