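# ggplot2 quick-look figures for each result type.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an availability profile
#'
#' Available and cumulative fractions by availability rank; the dashed line
#' marks the last rank with a positive cumulative fraction (the complete-case
#' core).
#'
#' @param object An [availability_profile()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot availability_profile
#' @export
autoplot.availability_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("rank", "fraction", "cumulative_fraction")],
    cols = c("fraction", "cumulative_fraction"),
    names_to = "measure", values_to = "value")
  core_rank <- max(c(0L, object$rank[object$cumulative_fraction > 0]))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$value,
                                          color = .data$measure)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "outcome rank (decreasing availability)",
                  y = "fraction of mice", color = NULL) +
    ggplot2::theme_minimal()
  if (core_rank > 0L) {
    p <- p + ggplot2::geom_vline(xintercept = core_rank + 0.5, linetype = "dashed")
  }
  p
}

#' Plot principal component scores with group ellipses
#'
#' @param object An `outcome_pca` from [pca_outcomes()].
#' @param grouping Optional group label per mouse; when given, 1-SD ellipse
#'   paths from [group_summary()] are overlaid.
#' @param components Two components to plot (default 1:2).
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot outcome_pca
#' @export
autoplot.outcome_pca <- function(object, grouping = NULL,
                                 components = c(1L, 2L), ...) {
  xy <- tibble::tibble(
    x = object$scores[, components[[1]]],
    y = object$scores[, components[[2]]],
    group = if (is.null(grouping)) "all" else as.character(grouping)
  )
  lab <- sprintf("PC%d (%.1f%%)", components,
                 100 * object$var_explained[components])
  p <- ggplot2::ggplot(xy, ggplot2::aes(x = .data$x, y = .data$y,
                                        color = .data$group)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = lab[[1]], y = lab[[2]], color = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(grouping)) {
    ell <- group_summary(object$scores, grouping, components)
    if (NROW(ell) > 0L) {
      theta <- seq(0, 2 * pi, length.out = 120)
      paths <- dplyr::bind_rows(lapply(seq_len(nrow(ell)), function(i) {
        e <- ell[i, ]
        tibble::tibble(
          group = e$group,
          x = e$mean_x + e$axis_major * cos(theta) * cos(e$angle) -
            e$axis_minor * sin(theta) * sin(e$angle),
          y = e$mean_y + e$axis_major * cos(theta) * sin(e$angle) +
            e$axis_minor * sin(theta) * cos(e$angle))
      }))
      p <- p + ggplot2::geom_path(data = paths,
                                  ggplot2::aes(x = .data$x, y = .data$y,
                                               color = .data$group))
    }
  }
  p
}

#' Plot a fitted AUC time trend
#'
#' Per-week AUC means with the fitted parabola and the optimal week.
#'
#' @param object A `time_trend` from [fit_time_trend()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot time_trend
#' @export
autoplot.time_trend <- function(object, ...) {
  pts <- object$points
  cf <- object$coefficients
  grid <- tibble::tibble(week = seq(min(pts$week), max(pts$week), length.out = 100))
  grid$auc <- cf[["a"]] + cf[["b"]] * grid$week + cf[["c"]] * grid$week^2
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$week, y = .data$auc_mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$auc)) +
    ggplot2::geom_vline(xintercept = object$optimal_week, linetype = "dashed") +
    ggplot2::labs(x = "week after first procedure", y = "bootstrapped AUC",
                  title = object$family) +
    ggplot2::theme_minimal()
  if ("auc_sd" %in% names(pts)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$auc_mean - .data$auc_sd,
                   ymax = .data$auc_mean + .data$auc_sd), width = 0.4)
  }
  p
}

#' Plot an ARI combination scan
#'
#' ARI distribution by combination size.
#'
#' @param object An `ari_scan` from [combination_scan()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot ari_scan
#' @export
autoplot.ari_scan <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = factor(.data$size), y = .data$ari)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "behavioral outcomes in combination",
                  y = "adjusted Rand index vs TBI/sham") +
    ggplot2::theme_minimal()
}

#' Plot a study-accumulation result
#'
#' Standardized RMSE distribution by number of pooled studies.
#'
#' @param object An `accumulation_result` from [accumulate_studies()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot accumulation_result
#' @export
autoplot.accumulation_result <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = factor(.data$m), y = .data$srmse)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "studies pooled",
                  y = paste0("standardized RMSE (", object$outcome, ")")) +
    ggplot2::theme_minimal()
}
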