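# Cohort assembly: per-mouse metadata plus a long table of behavioral
# measurements keyed by outcome code. Missingness is encoded by the absence of
# a measurement row; there are no sentinel values.

#' Assemble a cohort
#'
#' Validates and bundles the two cohort tables. Duplicated (mouse, code)
#' measurements, measurements for unknown mice, and codes that fail the
#' registry grammar are errors.
#'
#' @param mice Data frame with columns `mouse_id`, `experiment_id`, `group`
#'   (`"TBI"`/`"sham"`), `drop_height_in`, `n_hits`, `schedule`, `age_weeks`,
#'   `treatment`, `treatment_route`.
#' @param measurements Data frame with columns `mouse_id`, `outcome_code`,
#'   `value`.
#' @param registry Registry tibble used to validate codes; codes need not all
#'   appear in the registry's design, but must parse.
#' @return A `tbi_cohort` object: a list with tibbles `mice` and
#'   `measurements` and the `registry`.
#' @export
tbi_cohort <- function(mice, measurements, registry = default_registry()) {
  mice <- tibble::as_tibble(mice)
  measurements <- tibble::as_tibble(measurements)
  need_mice <- c("mouse_id", "experiment_id", "group", "drop_height_in",
                 "n_hits", "schedule", "age_weeks", "treatment", "treatment_route")
  missing_cols <- setdiff(need_mice, names(mice))
  if (length(missing_cols) > 0L) {
    stop("mice table lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  need_meas <- c("mouse_id", "outcome_code", "value")
  missing_cols <- setdiff(need_meas, names(measurements))
  if (length(missing_cols) > 0L) {
    stop("measurements table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(mice$mouse_id)) {
    stop("duplicate mouse_id in mice table: ",
         paste(unique(mice$mouse_id[duplicated(mice$mouse_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(mice$group %in% c("TBI", "sham"))) {
    stop("group must be 'TBI' or 'sham'", call. = FALSE)
  }
  if (any((mice$group == "sham") != (mice$drop_height_in == 0))) {
    stop("sham mice must have drop height 0 and TBI mice a positive drop height",
         call. = FALSE)
  }
  if (any(mice$n_hits < 1L)) stop("n_hits must be >= 1", call. = FALSE)
  key <- paste(measurements$mouse_id, measurements$outcome_code, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (mouse, code) measurements: ",
         paste(utils::head(gsub("\r", " / ", dup), 5L), collapse = "; "), call. = FALSE)
  }
  unknown <- setdiff(measurements$mouse_id, mice$mouse_id)
  if (length(unknown) > 0L) {
    stop("measurements refer to unknown mice: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  parse_code(unique(measurements$outcome_code))  # grammar validation
  measurements$value <- as.double(measurements$value)
  structure(
    list(mice = mice, measurements = measurements, registry = registry),
    class = "tbi_cohort"
  )
}

#' @export
print.tbi_cohort <- function(x, ...) {
  cat("<tbi_cohort> ", nrow(x$mice), " mice (",
      sum(x$mice$group == "TBI"), " TBI / ", sum(x$mice$group == "sham"),
      " sham), ", length(unique(x$mice$experiment_id)), " experiments, ",
      nrow(x$measurements), " measurements on ",
      length(unique(x$measurements$outcome_code)), " outcome codes\n", sep = "")
  invisible(x)
}

#' Read a cohort from CSV files
#'
#' @param mice_path,measurements_path Paths to UTF-8 CSV files with header
#'   rows ("." decimal separator).
#' @param registry Registry tibble.
#' @return A [tbi_cohort()] object.
#' @export
read_cohort <- function(mice_path, measurements_path, registry = default_registry()) {
  mice <- readr::read_csv(mice_path, show_col_types = FALSE, progress = FALSE)
  meas <- readr::read_csv(measurements_path, show_col_types = FALSE, progress = FALSE)
  tbi_cohort(mice, meas, registry)
}

#' Write a cohort to CSV files
#'
#' @param cohort A `tbi_cohort`.
#' @param dir Output directory (created if absent). Writes `mice.csv` and
#'   `measurements.csv`.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tbi_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("mice.csv", "measurements.csv"))
  readr::write_csv(cohort$mice, paths[[1]], progress = FALSE)
  readr::write_csv(cohort$measurements, paths[[2]], progress = FALSE)
  invisible(paths)
}

#' Wide table of a cohort
#'
#' Pivots the long measurement table to one row per mouse with one column per
#' outcome code (missing measurement = `NA`), joined to the mouse metadata.
#'
#' @param cohort A `tbi_cohort`.
#' @param codes Codes to include as columns; default all measured codes
#'   (canonical order).
#' @return A tibble: mouse metadata columns followed by one numeric column per
#'   code.
#' @export
cohort_table <- function(cohort, codes = NULL) {
  stopifnot(inherits(cohort, "tbi_cohort"))
  if (is.null(codes)) codes <- sort(unique(cohort$measurements$outcome_code))
  meas <- dplyr::filter(cohort$measurements, .data$outcome_code %in% codes)
  wide <- tidyr::pivot_wider(meas, id_cols = "mouse_id",
                             names_from = "outcome_code", values_from = "value")
  for (cd in setdiff(codes, names(wide))) wide[[cd]] <- NA_real_
  out <- dplyr::left_join(cohort$mice, wide, by = "mouse_id")
  out[, c(names(cohort$mice), codes)]
}

#' Availability and cumulative-fraction profile
#'
#' For each outcome code, the fraction of mice with a measurement ("available
#' fraction"); codes are ranked by decreasing availability (ties broken by
#' canonical code string) and the cumulative fraction at rank k is the
#' fraction of mice measured on all of the top-k codes. The largest rank with
#' cumulative fraction > 0 identifies the maximal complete-case core.
#'
#' @param cohort A `tbi_cohort`.
#' @param codes Codes to profile. Default: non-severity, non-redundant codes
#'   present in the measurements.
#' @return A tibble of class `availability_profile` with columns `rank`,
#'   `code`, `n_available`, `fraction`, `n_cumulative`, `cumulative_fraction`.
#' @export
availability_profile <- function(cohort, codes = NULL) {
  stopifnot(inherits(cohort, "tbi_cohort"))
  if (nrow(cohort$mice) == 0L) stop("empty cohort", call. = FALSE)
  if (is.null(codes)) {
    codes <- intersect(behavioral_codes(cohort$registry),
                       unique(cohort$measurements$outcome_code))
  }
  n_mice <- nrow(cohort$mice)
  meas <- dplyr::filter(cohort$measurements, .data$outcome_code %in% codes)
  counts <- meas |>
    dplyr::count(.data$outcome_code, name = "n_available")
  counts <- dplyr::left_join(tibble::tibble(outcome_code = codes), counts,
                             by = "outcome_code")
  counts$n_available[is.na(counts$n_available)] <- 0L
  ord <- order(-counts$n_available, counts$outcome_code)
  counts <- counts[ord, ]
  # cumulative: mice measured on every code of the top-k set
  sets <- split(meas$mouse_id, meas$outcome_code)
  cum_ids <- cohort$mice$mouse_id
  n_cum <- integer(nrow(counts))
  for (k in seq_len(nrow(counts))) {
    ids <- sets[[counts$outcome_code[[k]]]]
    if (is.null(ids)) ids <- character(0)
    cum_ids <- intersect(cum_ids, ids)
    n_cum[[k]] <- length(cum_ids)
  }
  out <- tibble::tibble(
    rank = seq_len(nrow(counts)),
    code = counts$outcome_code,
    n_available = counts$n_available,
    fraction = counts$n_available / n_mice,
    n_cumulative = n_cum,
    cumulative_fraction = n_cum / n_mice
  )
  class(out) <- c("availability_profile", class(out))
  out
}

#' Codes of the maximal complete-case core
#'
#' The top-availability codes whose cumulative fraction is still positive,
#' i.e. the largest prefix of the availability ranking on which a nonempty
#' complete-case subset exists.
#'
#' @param profile An [availability_profile()].
#' @return Character vector of codes (in availability rank order).
#' @export
core_codes <- function(profile) {
  stopifnot(inherits(profile, "availability_profile"))
  profile$code[profile$cumulative_fraction > 0]
}

#' Complete-case subset of a cohort
#'
#' Retains exactly the mice with a measurement for every requested code, and
#' restricts the measurements to those codes. The result may be empty.
#'
#' @param cohort A `tbi_cohort`.
#' @param codes Character vector of codes (must be measured codes or at least
#'   valid code strings).
#' @return A `tbi_cohort` containing the complete-case mice and only the
#'   requested codes.
#' @export
complete_case_subset <- function(cohort, codes) {
  stopifnot(inherits(cohort, "tbi_cohort"), length(codes) > 0L)
  meas <- dplyr::filter(cohort$measurements, .data$outcome_code %in% codes)
  counts <- meas |> dplyr::count(.data$mouse_id)
  keep <- counts$mouse_id[counts$n == length(codes)]
  structure(
    list(
      mice = dplyr::filter(cohort$mice, .data$mouse_id %in% keep),
      measurements = dplyr::filter(meas, .data$mouse_id %in% keep),
      registry = cohort$registry
    ),
    class = "tbi_cohort"
  )
}

#' Number of complete cases on a code set
#'
#' @param cohort A `tbi_cohort`.
#' @param codes Character vector of codes.
#' @return Integer count of mice measured on every code in `codes`.
#' @export
n_complete_cases <- function(cohort, codes) {
  if (length(codes) == 0L) return(nrow(cohort$mice))
  meas <- dplyr::filter(cohort$measurements, .data$outcome_code %in% codes)
  sum(table(meas$mouse_id) == length(codes))
}
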