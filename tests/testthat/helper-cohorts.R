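# Small cohort builders used across tests.

# Mouse metadata table with minimal valid fields.
make_mice <- function(n, groups = rep(c("TBI", "sham"), length.out = n),
                      experiment = "E1", n_hits = 5L, treatment = "none") {
  tibble::tibble(
    mouse_id = sprintf("m%03d", seq_len(n)),
    experiment_id = rep(experiment, length.out = n),
    group = groups,
    drop_height_in = ifelse(groups == "TBI", 42, 0),
    n_hits = rep(n_hits, length.out = n),
    schedule = "5_in_5_days",
    age_weeks = 8L,
    treatment = rep(treatment, length.out = n),
    treatment_route = "none"
  )
}

# Cohort from a values matrix (rows = mice, cols = codes); NA = missing.
cohort_from_matrix <- function(values, codes,
                               groups = rep(c("TBI", "sham"),
                                            length.out = nrow(values)),
                               experiment = "E1", n_hits = 5L) {
  mice <- make_mice(nrow(values), groups, experiment, n_hits)
  idx <- which(!is.na(values), arr.ind = TRUE)
  meas <- tibble::tibble(
    mouse_id = mice$mouse_id[idx[, 1]],
    outcome_code = codes[idx[, 2]],
    value = values[idx]
  )
  tbi_cohort(mice, meas)
}

# Wide data frame with group labels, n_hits and p feature columns carrying a
# standardized group separation `effect` on every feature.
make_classif_data <- function(n, p = 1, effect = 0, seed = 1,
                              balance = 0.5) {
  set.seed(seed)
  n_tbi <- round(n * balance)
  group <- c(rep("TBI", n_tbi), rep("sham", n - n_tbi))
  x <- matrix(rnorm(n * p), n, p) + effect * (group == "TBI")
  colnames(x) <- sprintf("MWM:H%d:W2", seq_len(p))
  out <- tibble::as_tibble(x)
  out$group <- group
  out$n_hits <- sample(1:5, n, replace = TRUE)
  out
}

# Brute-force complete-case row scan (independent oracle).
brute_complete_rows <- function(values) {
  which(apply(values, 1, function(r) !anyNA(r)))
}

# Brute-force maximum-model search by full subset enumeration (independent
# oracle for maximum_model, feasible for <= 14 candidates).
brute_maximum_model <- function(cohort, candidates, min_per_variable = 10,
                                n_adjust = 1) {
  best <- NULL
  candidates <- sort(candidates)
  for (s in seq_along(candidates)) {
    for (cmb in utils::combn(candidates, s, simplify = FALSE)) {
      n <- n_complete_cases(cohort, cmb)
      if (n < min_per_variable * (s + n_adjust)) next
      if (is.null(best) || s > length(best$set) ||
          (s == length(best$set) && n > best$n) ||
          (s == length(best$set) && n == best$n &&
           paste(cmb, collapse = ",") < paste(best$set, collapse = ","))) {
        best <- list(set = cmb, n = n)
      }
    }
  }
  if (is.null(best)) character(0) else best$set
}

# Brute-force AUC by explicit pair counting (independent oracle).
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}
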