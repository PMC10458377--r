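# Unsupervised structure detection: k-means over combinations of the core
# outcomes, scored against the TBI/sham labels by the adjusted Rand index.

#' Adjusted Rand index (Hubert-Arabie)
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the contingency table: 1 for identical partitions, 0 in
#' expectation for independent random partitions, negative for agreement
#' below chance. Symmetric and invariant to label renaming.
#'
#' @param a,b Vectors of cluster labels (any type), equal length >= 2.
#' @return The ARI (<= 1).
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length", call. = FALSE)
  n <- length(a)
  stopifnot(n >= 2L)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Seeded k-means partition
#'
#' Hartigan-Wong k-means on Euclidean distances, best of `restarts` random
#' initializations by within-cluster sum of squares, under a fixed seed.
#'
#' @param x Numeric matrix (rows = mice), typically scaled.
#' @param k Number of clusters (default 2, the injured/uninjured target
#'   structure).
#' @param restarts Random initializations (default 10).
#' @param seed Integer seed.
#' @return Integer vector of cluster labels (1..k).
#' @export
kmeans_partition <- function(x, k = 2, restarts = 10, seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) < k) stop("fewer rows than clusters", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(.derive_seed(seed, "kmeans"), kind = "Mersenne-Twister")
  n_distinct <- nrow(unique(x))
  if (n_distinct < k) stop("fewer distinct rows than clusters", call. = FALSE)
  fit <- stats::kmeans(x, centers = k, nstart = restarts,
                       algorithm = "Hartigan-Wong", iter.max = 50)
  unname(fit$cluster)
}

#' k-means / ARI scan over outcome combinations
#'
#' For every combination of the given outcome codes (optionally restricted by
#' size or subsampled per size), takes the complete cases, rescales and
#' outlier-trims that subset on its own, partitions the mice by k-means, and
#' scores the partition against the TBI/sham labels with the adjusted Rand
#' index. With 15 codes the full scan covers 2^15 - 1 = 32,767 combinations.
#'
#' @param cohort A `tbi_cohort`.
#' @param codes Outcome codes to scan (e.g. the 15-variable complete-case
#'   core).
#' @param k Clusters (default 2).
#' @param restarts k-means restarts per combination (default 10).
#' @param seed Integer seed; each combination derives its own stream.
#' @param sizes Combination sizes to include (default all `1:length(codes)`).
#' @param max_per_size If finite, randomly subsample at most this many
#'   combinations per size (without replacement); the full count per size is
#'   still reported.
#' @param z_max Outlier threshold passed to [scale_and_trim()].
#' @return An `ari_scan`: list with `results` (one row per evaluated
#'   combination: `size`, `codes`, `ari`, `n`) and `size_summary` (per size:
#'   total combinations `n_combinations`, `n_evaluated`, median and quartiles
#'   of ARI).
#' @export
combination_scan <- function(cohort, codes, k = 2, restarts = 10, seed = 1,
                             sizes = NULL, max_per_size = Inf, z_max = 5) {
  stopifnot(inherits(cohort, "tbi_cohort"), length(codes) >= 1L)
  codes <- sort(unique(codes))
  p <- length(codes)
  if (is.null(sizes)) sizes <- seq_len(p)
  full <- complete_case_subset(cohort, codes)
  if (nrow(full$mice) == 0L) stop("no complete cases on the scan codes", call. = FALSE)
  wide <- cohort_table(full, codes)
  labels <- wide$group
  xmat <- as.matrix(wide[, codes, drop = FALSE])
  rownames(xmat) <- wide$mouse_id

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)

  rows <- list()
  for (s in sizes) {
    combos <- utils::combn(p, s, simplify = FALSE)
    if (is.finite(max_per_size) && length(combos) > max_per_size) {
      set.seed(.derive_seed(seed, paste0("scan_sample:", s)), kind = "Mersenne-Twister")
      combos <- combos[sort(sample.int(length(combos), max_per_size))]
    }
    for (ci in seq_along(combos)) {
      idx <- combos[[ci]]
      sub <- xmat[, idx, drop = FALSE]
      st <- tryCatch(scale_and_trim(sub, z_max = z_max), error = function(e) NULL)
      if (is.null(st)) next
      keep <- rownames(st$values)
      lab <- labels[match(keep, rownames(xmat))]
      cl <- tryCatch(
        kmeans_partition(st$values, k = k, restarts = restarts,
                         seed = .derive_seed(seed, paste(codes[idx], collapse = "|"))),
        error = function(e) NULL
      )
      if (is.null(cl)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        size = s, codes = list(codes[idx]),
        ari = adjusted_rand_index(cl, lab), n = length(cl)
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  size_summary <- results |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(
      n_evaluated = dplyr::n(),
      ari_median = stats::median(.data$ari),
      ari_q1 = unname(stats::quantile(.data$ari, 0.25)),
      ari_q3 = unname(stats::quantile(.data$ari, 0.75)),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_combinations = choose(p, .data$size), .after = "size")
  structure(list(results = results, size_summary = size_summary,
                 k = k, codes = codes),
            class = "ari_scan")
}

#' Combination counts per size
#'
#' The number of distinct outcome combinations at each size for a core of
#' `p` outcomes — the combinatorial budget of a full [combination_scan()].
#'
#' @param p Number of outcomes in the core.
#' @return A tibble with `size`, `n_combinations`, and the running `total`.
#' @export
scan_combination_counts <- function(p) {
  sizes <- seq_len(p)
  n <- choose(p, sizes)
  tibble::tibble(size = sizes, n_combinations = n, total = cumsum(n))
}
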