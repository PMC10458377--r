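# Standardization, outlier screening and PCA summaries of the complete-case
# outcome matrix.

#' Unit-variance scaling with a 5-SD outlier screen
#'
#' Computes z-scores once on the input; any row (mouse) with |z| > `z_max` on
#' any column is dropped entirely, and the remaining data are re-centered and
#' re-scaled to unit variance. The screen is a single pass: it is not iterated
#' on the rescaled data, so the operation is idempotent on its own output.
#'
#' @param x A numeric matrix (rows = mice, columns = outcome codes, row and
#'   column names set) or a data frame of numeric columns; no missing values.
#' @param z_max Outlier threshold in SD units (default 5).
#' @return A `scaled_matrix`: list with `values` (scaled matrix), `center` and
#'   `scale` (per-column statistics of the retained rows), and `removed`
#'   (tibble logging each dropped row with the offending code and z-score).
#' @export
scale_and_trim <- function(x, z_max = 5) {
  if (is.data.frame(x)) x <- as.matrix(x)
  stopifnot(is.numeric(x), nrow(x) >= 2L)
  if (anyNA(x)) stop("scale_and_trim requires complete-case input", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  s0 <- apply(x, 2, stats::sd)
  if (any(s0 == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(x)[s0 == 0], collapse = ", "), call. = FALSE)
  }
  z <- sweep(sweep(x, 2, colMeans(x)), 2, s0, "/")
  bad <- abs(z) > z_max
  drop_row <- rowSums(bad) > 0
  removed <- if (any(drop_row)) {
    idx <- which(bad & drop_row, arr.ind = TRUE)
    tibble::tibble(row = rownames(x)[idx[, 1]],
                   code = colnames(x)[idx[, 2]],
                   z = z[idx])
  } else {
    tibble::tibble(row = character(), code = character(), z = numeric())
  }
  kept <- x[!drop_row, , drop = FALSE]
  if (nrow(kept) < 2L) stop("fewer than 2 rows remain after outlier removal", call. = FALSE)
  ctr <- colMeans(kept)
  scl <- apply(kept, 2, stats::sd)
  if (any(scl == 0)) {
    stop("zero-variance column(s) after outlier removal: ",
         paste(colnames(kept)[scl == 0], collapse = ", "), call. = FALSE)
  }
  structure(
    list(values = sweep(sweep(kept, 2, ctr), 2, scl, "/"),
         center = ctr, scale = scl, removed = removed),
    class = "scaled_matrix"
  )
}

#' Principal component analysis of a scaled outcome matrix
#'
#' PCA by singular value decomposition of the unit-variance matrix (equivalent
#' to an eigendecomposition of the correlation matrix). Components are ordered
#' by decreasing explained variance; the sign of each loading vector is fixed
#' so its largest-magnitude entry is positive. The outcome-component
#' correlation matrix (Pearson correlation of each original column with each
#' score vector) summarizes what each component carries.
#'
#' @param s A `scaled_matrix` from [scale_and_trim()], or a bare numeric
#'   matrix already scaled.
#' @return An `outcome_pca`: list with `loadings` (orthonormal columns),
#'   `scores`, `var_explained` (fractions summing to 1), and `correlations`
#'   (outcomes x components).
#' @export
pca_outcomes <- function(s) {
  x <- if (inherits(s, "scaled_matrix")) s$values else as.matrix(s)
  stopifnot(nrow(x) >= 2L)
  sv <- svd(scale(x, center = TRUE, scale = FALSE))
  d <- sv$d
  if (max(d) <= 1e-12) stop("degenerate input: rank 0", call. = FALSE)
  k <- ncol(sv$v)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  loadings <- sweep(sv$v, 2, flip, "*")
  scores <- sweep(sv$u %*% diag(d, k, k), 2, flip, "*")
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(k)))
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  var_explained <- d^2 / sum(d^2)
  keep <- d > 1e-12 * max(d)
  correlations <- suppressWarnings(stats::cor(x, scores[, keep, drop = FALSE]))
  structure(
    list(loadings = loadings, scores = scores,
         var_explained = var_explained, correlations = correlations),
    class = "outcome_pca"
  )
}

#' Per-group centroids and 68% (1-SD) ellipses in component space
#'
#' Summarizes groups of mice in the plane of two principal component scores:
#' group centroid, 2x2 within-group covariance, and the 1-standard-deviation
#' ellipse (axes = principal SDs of the within-group score covariance, i.e. a
#' 68%-style dispersion ellipse, not a standard-error ellipse). Groups with a
#' single mouse are skipped with a warning.
#'
#' @param scores Score matrix (mice x components) from [pca_outcomes()].
#' @param grouping Vector of group labels, one per mouse.
#' @param components Which two components to summarize (default 1:2).
#' @return A tibble: `group`, `n`, centroid (`mean_x`, `mean_y`), covariance
#'   entries (`var_x`, `var_y`, `cov_xy`), ellipse semi-axes (`axis_major`,
#'   `axis_minor`) and orientation `angle` (radians).
#' @export
group_summary <- function(scores, grouping, components = c(1L, 2L)) {
  stopifnot(nrow(scores) == length(grouping), length(components) == 2L)
  xy <- scores[, components, drop = FALSE]
  groups <- split(seq_len(nrow(xy)), grouping)
  rows <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    if (length(i) < 2L) {
      warning("group '", g, "' has a single mouse; skipped", call. = FALSE)
      return(NULL)
    }
    m <- colMeans(xy[i, , drop = FALSE])
    v <- stats::cov(xy[i, , drop = FALSE])
    e <- eigen(v, symmetric = TRUE)
    tibble::tibble(
      group = g, n = length(i),
      mean_x = m[[1]], mean_y = m[[2]],
      var_x = v[1, 1], var_y = v[2, 2], cov_xy = v[1, 2],
      axis_major = sqrt(max(e$values[[1]], 0)),
      axis_minor = sqrt(max(e$values[[2]], 0)),
      angle = atan2(e$vectors[2, 1], e$vectors[1, 1])
    )
  })
  dplyr::bind_rows(rows)
}

#' Row ordering from complete-linkage hierarchical clustering
#'
#' Orders the rows of an outcome-component correlation matrix by
#' complete-linkage hierarchical clustering on Euclidean distances between
#' rows — the ordering a clustered heatmap of the correlations would use.
#'
#' @param c_matrix Numeric matrix (e.g. the `correlations` element of an
#'   [pca_outcomes()] result) with at least 2 rows.
#' @return A list with `order` (permutation of row indices), `labels` (row
#'   names in that order) and `hclust` (the dendrogram object, merge heights
#'   non-decreasing).
#' @export
correlation_ordering <- function(c_matrix) {
  stopifnot(nrow(c_matrix) >= 2L)
  hc <- stats::hclust(stats::dist(c_matrix, method = "euclidean"),
                      method = "complete")
  list(order = hc$order,
       labels = if (!is.null(rownames(c_matrix))) rownames(c_matrix)[hc$order],
       hclust = hc)
}
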