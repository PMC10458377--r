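# End-to-end orchestration: one configuration object, one call running every
# stage, and a flat CSV/JSON report bundle any external viewer can consume.

#' Pipeline configuration
#'
#' Collects every stage parameter with its standard default: 25 bootstrap
#' iterations, 10 cross-validation folds, qualification threshold 0.75,
#' 25 random study subsets with 10 bootstrap iterations in the accumulation
#' analysis, outlier screen at 5 SD, k = 2 clusters with 10 restarts, and
#' 10 mice per variable.
#'
#' @param seed Global seed; each stage derives its own stream.
#' @param boot_iterations,cv_folds,threshold,min_per_variable Classification
#'   and selection parameters.
#' @param k,restarts,scan_max_per_size Clustering scan parameters.
#' @param study_subsets,accumulation_iterations,accumulation_outcome
#'   Accumulation parameters.
#' @param z_max Outlier threshold (SD units).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, boot_iterations = 25, cv_folds = 10,
                       threshold = 0.75, min_per_variable = 10,
                       k = 2, restarts = 10, scan_max_per_size = 200,
                       study_subsets = 25, accumulation_iterations = 10,
                       accumulation_outcome = "MWM:H4:W2", z_max = 5) {
  structure(
    list(seed = seed, boot_iterations = boot_iterations, cv_folds = cv_folds,
         threshold = threshold, min_per_variable = min_per_variable,
         k = k, restarts = restarts, scan_max_per_size = scan_max_per_size,
         study_subsets = study_subsets,
         accumulation_iterations = accumulation_iterations,
         accumulation_outcome = accumulation_outcome, z_max = z_max),
    class = "run_config"
  )
}

#' Write/read a configuration
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `write_config` returns the path invisibly; `read_config` returns a
#'   `run_config` equivalent to the one written.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run every analysis stage on a cohort
#'
#' Executes the full pipeline — availability profile, PCA summary of the
#' complete-case core, per-family AUC time trends, the selection cascade, the
#' k-means/ARI combination scan, and the study-accumulation analysis — and
#' optionally writes a report bundle (CSV per table plus a JSON summary
#' stamped with the seed and configuration).
#'
#' @param cohort A `tbi_cohort`.
#' @param config A [run_config()].
#' @param out_dir Optional directory for the report bundle.
#' @return A `pipeline_result` list with elements `availability`, `pca`,
#'   `trends`, `selection`, `scan`, `accumulation`, `config`.
#' @export
run_all <- function(cohort, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(cohort, "tbi_cohort"), inherits(config, "run_config"))
  prof <- availability_profile(cohort)
  core <- core_codes(prof)
  pca <- NULL
  if (length(core) >= 2L) {
    cc <- complete_case_subset(cohort, core)
    if (nrow(cc$mice) >= 3L) {
      wide <- cohort_table(cc, core)
      st <- scale_and_trim(as.matrix(wide[, core]), z_max = config$z_max)
      pca <- pca_outcomes(st)
    }
  }
  trends <- auc_time_trends(cohort, B = config$boot_iterations,
                            seed = .derive_seed(config$seed, "stage:trends"),
                            min_per_variable = config$min_per_variable)
  selection <- run_cascade(cohort, B = config$boot_iterations,
                           threshold = config$threshold,
                           seed = .derive_seed(config$seed, "stage:select"),
                           min_per_variable = config$min_per_variable)
  scan <- if (length(core) >= 1L) {
    combination_scan(cohort, core, k = config$k, restarts = config$restarts,
                     seed = .derive_seed(config$seed, "stage:cluster"),
                     max_per_size = config$scan_max_per_size,
                     z_max = config$z_max)
  }
  accumulation <- tryCatch(
    accumulate_studies(cohort, outcome = config$accumulation_outcome,
                       subsets_per_m = config$study_subsets,
                       B = config$accumulation_iterations,
                       seed = .derive_seed(config$seed, "stage:accumulate"),
                       z_max = config$z_max),
    error = function(e) NULL
  )
  result <- structure(
    list(availability = prof, pca = pca, trends = trends,
         selection = selection, scan = scan, accumulation = accumulation,
         config = config),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) export_report(result, out_dir)
  result
}

# Flatten a list-column of code vectors for CSV export.
.flatten_codes <- function(tbl) {
  for (col in intersect(c("variables", "adjustment", "maximum_model", "codes"),
                        names(tbl))) {
    tbl[[col]] <- vapply(tbl[[col]], paste, character(1), collapse = "|")
  }
  tbl
}

#' Export a report bundle
#'
#' Writes each result table as CSV and a JSON summary (`report.json`) holding
#' the configuration, the seed, and the headline numbers.
#'
#' @param result A `pipeline_result` from [run_all()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_report <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(tbl, name) {
    if (is.null(tbl) || NROW(tbl) == 0L) return()
    p <- file.path(out_dir, name)
    readr::write_csv(.flatten_codes(tibble::as_tibble(tbl)), p, progress = FALSE)
    paths <<- c(paths, p)
  }
  wr(result$availability, "availability.csv")
  if (!is.null(result$pca)) {
    wr(tibble::as_tibble(result$pca$correlations, rownames = "code"),
       "pca_correlations.csv")
    wr(tibble::tibble(component = seq_along(result$pca$var_explained),
                      var_explained = result$pca$var_explained),
       "pca_variance.csv")
  }
  wr(result$trends$points, "auc_by_family_week.csv")
  wr(result$selection$level3, "selection_level3.csv")
  wr(result$selection$level2, "selection_level2.csv")
  wr(result$selection$level1, "selection_level1.csv")
  if (!is.null(result$scan)) {
    wr(result$scan$results, "ari_scan.csv")
    wr(result$scan$size_summary, "ari_scan_summary.csv")
  }
  if (!is.null(result$accumulation)) {
    wr(result$accumulation$results, "accumulation.csv")
    wr(result$accumulation$m_summary, "accumulation_summary.csv")
  }
  summary <- list(
    config = unclass(result$config),
    n_core_codes = length(core_codes(result$availability)),
    level1 = if (NROW(result$selection$level1) > 0L) {
      lapply(seq_len(nrow(result$selection$level1)), function(i) {
        r <- result$selection$level1[i, ]
        list(category = r$key, variables = r$variables[[1]],
             auc_mean = r$auc_mean, auc_sd = r$auc_sd, n = r$n_total,
             qualified = r$qualified)
      })
    } else list()
  )
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(summary, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, jp))
}
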