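# Does pooling heterogeneous experiments predict a behavioral outcome better
# than single experiments? Study-accumulation linear models scored by
# standardized RMSE.

#' Standardized root-mean-square error
#'
#' RMSE of the predictions divided by the standard deviation (sample SD,
#' n - 1 denominator) of the observations; ~1 means no better than
#' predicting the mean.
#'
#' @param predictions,observations Numeric vectors of equal length >= 2.
#' @param sd_reference Optional SD to standardize by (default: SD of
#'   `observations`); the accumulation analysis passes the pooled-subset SD
#'   so curves are comparable across study counts.
#' @return Standardized RMSE (>= 0). Zero SD is an error.
#' @export
standardized_rmse <- function(predictions, observations, sd_reference = NULL) {
  stopifnot(length(predictions) == length(observations), length(observations) >= 2L || !is.null(sd_reference))
  s <- if (is.null(sd_reference)) stats::sd(observations) else sd_reference
  if (!is.finite(s) || s <= 0) stop("observation SD must be positive", call. = FALSE)
  sqrt(mean((predictions - observations)^2)) / s
}

# Wide per-mouse analysis table for the accumulation model: outcome value,
# LOC after the first procedure, number of procedures, treatment.
.accumulation_table <- function(cohort, outcome, loc_code = "LOC:1:W0") {
  meas <- cohort$measurements
  out_val <- meas[meas$outcome_code == outcome, c("mouse_id", "value")]
  names(out_val)[2] <- "outcome"
  loc_val <- meas[meas$outcome_code == loc_code, c("mouse_id", "value")]
  names(loc_val)[2] <- "loc_first"
  tbl <- dplyr::inner_join(out_val, loc_val, by = "mouse_id")
  tbl <- dplyr::inner_join(
    tbl, cohort$mice[, c("mouse_id", "experiment_id", "n_hits", "treatment")],
    by = "mouse_id")
  tbl[stats::complete.cases(tbl), ]
}

#' Study-accumulation analysis of predictive error
#'
#' For each number of studies m (1..`max_studies`), draws up to
#' `subsets_per_m` distinct random subsets of m eligible experiments, pools
#' their mice (complete cases on the outcome and predictors, outcome outliers
#' beyond `z_max` SD removed), and for each subset runs `B` bootstrap
#' iterations of an ordinary least-squares model predicting the outcome from
#' loss of consciousness after the first procedure, the number of procedures,
#' and treatment (one-hot, "none" as reference). Each iteration's
#' standardized RMSE is evaluated on the out-of-bag mice, standardized by the
#' pooled subset's outcome SD.
#'
#' @param cohort A `tbi_cohort`.
#' @param outcome Outcome code to predict (default `"MWM:H4:W2"`).
#' @param max_studies Largest number of studies to pool (default: all
#'   eligible experiments).
#' @param subsets_per_m Random study subsets per m (default 25).
#' @param B Bootstrap iterations per subset (default 10).
#' @param seed Integer seed.
#' @param z_max Outlier threshold on the pooled outcome (default 5).
#' @param loc_code Code providing the loss-of-consciousness predictor
#'   (default `"LOC:1:W0"`).
#' @return An `accumulation_result`: list with `results` (one row per
#'   (m, subset, iteration): `m`, `subset_id`, `studies`, `n`, `iteration`,
#'   `srmse`), `m_summary` (median and quartiles per m), `eligible`
#'   (experiment ids), and a `skipped` log of subsets too small to fit.
#' @export
accumulate_studies <- function(cohort, outcome = "MWM:H4:W2",
                               max_studies = NULL, subsets_per_m = 25,
                               B = 10, seed = 1, z_max = 5,
                               loc_code = "LOC:1:W0") {
  stopifnot(inherits(cohort, "tbi_cohort"))
  tbl <- .accumulation_table(cohort, outcome, loc_code)
  if (nrow(tbl) == 0L) stop("no mouse has both the outcome and the predictors", call. = FALSE)
  eligible <- sort(unique(tbl$experiment_id))
  if (is.null(max_studies)) max_studies <- length(eligible)
  max_studies <- min(max_studies, length(eligible))

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)

  rows <- list()
  skipped <- list()
  for (m in seq_len(max_studies)) {
    set.seed(.derive_seed(seed, paste0("accumulate:", m)), kind = "Mersenne-Twister")
    n_comb <- choose(length(eligible), m)
    subsets <- list()
    if (n_comb <= subsets_per_m) {
      subsets <- utils::combn(eligible, m, simplify = FALSE)
    } else {
      seen <- character(0)
      while (length(subsets) < subsets_per_m) {
        s <- sort(sample(eligible, m))
        key <- paste(s, collapse = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        subsets[[length(subsets) + 1L]] <- s
      }
    }
    for (si in seq_along(subsets)) {
      studies <- subsets[[si]]
      pool <- tbl[tbl$experiment_id %in% studies, ]
      # outcome outlier screen on the pooled subset
      if (nrow(pool) >= 2L) {
        z <- (pool$outcome - mean(pool$outcome)) / stats::sd(pool$outcome)
        if (any(is.finite(z))) pool <- pool[!is.finite(z) | abs(z) <= z_max, ]
      }
      trt <- factor(pool$treatment)
      if ("none" %in% levels(trt)) trt <- stats::relevel(trt, "none")
      df <- data.frame(loc_first = pool$loc_first, n_hits = pool$n_hits,
                       trt = trt)
      # a subset may contain a single treatment arm; the dummy block then
      # drops out rather than aborting the fit
      fml <- if (nlevels(droplevels(trt)) >= 2L) {
        ~ loc_first + n_hits + trt
      } else {
        ~ loc_first + n_hits
      }
      df$trt <- droplevels(trt)
      x <- stats::model.matrix(fml, data = df)
      n <- nrow(x)
      if (n < ncol(x) + 2L || stats::sd(pool$outcome) == 0) {
        skipped[[length(skipped) + 1L]] <- tibble::tibble(
          m = m, subset_id = si, n = n,
          reason = "too few pooled mice for the predictor set")
        next
      }
      sd_pool <- stats::sd(pool$outcome)
      for (b in seq_len(B)) {
        ok <- FALSE
        for (try in seq_len(10L)) {
          idx <- sample.int(n, n, replace = TRUE)
          oob <- setdiff(seq_len(n), idx)
          if (length(oob) < 1L) next
          fit <- stats::lm.fit(x[idx, , drop = FALSE], pool$outcome[idx])
          beta <- fit$coefficients
          beta[is.na(beta)] <- 0
          pred <- drop(x[oob, , drop = FALSE] %*% beta)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            m = m, subset_id = si, studies = paste(studies, collapse = "|"),
            n = n, iteration = b,
            srmse = standardized_rmse(pred, pool$outcome[oob],
                                      sd_reference = sd_pool))
          ok <- TRUE
          break
        }
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  m_summary <- results |>
    dplyr::group_by(.data$m) |>
    dplyr::summarise(
      n_values = dplyr::n(),
      srmse_median = stats::median(.data$srmse),
      srmse_q1 = unname(stats::quantile(.data$srmse, 0.25)),
      srmse_q3 = unname(stats::quantile(.data$srmse, 0.75)),
      n_median = stats::median(.data$n),
      .groups = "drop"
    )
  structure(
    list(results = results, m_summary = m_summary, eligible = eligible,
         outcome = outcome, skipped = dplyr::bind_rows(skipped)),
    class = "accumulation_result"
  )
}
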