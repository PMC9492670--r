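#' Pearson functional connectivity from an ROI time-series table
#'
#' Computes the product-moment correlation between every pair of regional
#' BOLD time series. The result is a symmetric matrix with unit diagonal —
#' the functional connectome of one subject.
#'
#' Regions whose signal is constant (zero variance) carry no correlation
#' information: by default every edge touching such a region is set to 0 and
#' a warning names the region; with `strict = TRUE` the input is rejected
#' instead.
#'
#' @param series A T x R data frame or matrix of BOLD signal (rows =
#'   timepoints, columns = regions). Column names are used as region labels.
#' @param strict If `TRUE`, zero-variance regions are an error.
#' @return An R x R numeric matrix of correlations with region labels as
#'   dimnames.
#' @export
#' @examples
#' ts <- matrix(rnorm(60), nrow = 20, ncol = 3)
#' pearson_fc(ts)
pearson_fc <- function(series, strict = FALSE) {
  x <- as.matrix(series)
  if (!is.numeric(x)) abort("time series must be numeric")
  if (nrow(x) < 3) abort("need at least 3 timepoints")
  if (ncol(x) < 2) abort("need at least 2 regions")
  if (anyNA(x)) abort("time series contains missing values")
  labels <- colnames(x)
  if (is.null(labels)) {
    width <- max(3L, nchar(as.character(ncol(x))))
    labels <- sprintf(paste0("ROI%0", width, "d"), seq_len(ncol(x)))
  }
  sds <- apply(x, 2, sd)
  flat <- which(sds == 0)
  if (length(flat) > 0) {
    if (strict) {
      abort(paste0("zero-variance region(s): ", paste(labels[flat], collapse = ", ")))
    }
    warn(paste0("zero-variance region(s) ", paste(labels[flat], collapse = ", "),
                "; their edges are set to 0"))
  }
  r <- suppressWarnings(cor(x))
  r[is.na(r)] <- 0
  diag(r) <- 1
  r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  dimnames(r) <- list(labels, labels)
  r
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Returns the strictly-upper-triangular entries in row-major order (row
#' index < column index), the single canonical edge ordering used
#' throughout the package. A 116-region connectome yields 6670 edge values.
#'
#' @param fc Symmetric R x R correlation matrix.
#' @param tol Maximum allowed asymmetry.
#' @return Named numeric vector of length `R*(R-1)/2`; names from
#'   [edge_names()].
#' @seealso [devectorize()] for the inverse.
#' @export
#' @examples
#' m <- diag(3); m[1, 2] <- m[2, 1] <- 0.5
#' vectorize_upper(m)
vectorize_upper <- function(fc, tol = 1e-10) {
  x <- as.matrix(fc)
  if (nrow(x) != ncol(x)) abort("connectivity matrix must be square")
  if (max(abs(x - t(x))) > tol) abort("connectivity matrix is not symmetric")
  n <- nrow(x)
  # row-major strict upper triangle: transpose trick (upper.tri by column of t)
  v <- t(x)[lower.tri(x)]
  names(v) <- edge_names(n, labels = colnames(x))
  v
}

#' Rebuild a connectivity matrix from its canonical edge vector
#'
#' Inverse of [vectorize_upper()]: places the edge values back into a
#' symmetric matrix with unit diagonal.
#'
#' @param edges Numeric vector of length `n_regions*(n_regions-1)/2` in
#'   canonical order.
#' @param n_regions Number of regions the vector encodes.
#' @param labels Optional region labels.
#' @return R x R symmetric numeric matrix with unit diagonal.
#' @export
#' @examples
#' devectorize(c(0.5), 2)
devectorize <- function(edges, n_regions, labels = NULL) {
  n_regions <- as.integer(n_regions)
  if (length(edges) != n_edges_for(n_regions)) {
    abort(sprintf("edge vector of length %d does not match n_regions = %d (expected %d)",
                  length(edges), n_regions, n_edges_for(n_regions)))
  }
  m <- matrix(0, n_regions, n_regions)
  m[lower.tri(m)] <- edges
  m <- m + t(m)
  diag(m) <- 1
  m <- t(m) # back to row-major upper convention (symmetric, so cosmetic)
  if (is.null(labels)) {
    width <- max(3L, nchar(as.character(n_regions)))
    labels <- sprintf(paste0("ROI%0", width, "d"), seq_len(n_regions))
  }
  dimnames(m) <- list(labels, labels)
  m
}

#' Per-subject Z-score normalization of an edge vector
#'
#' Standardizes one subject's edge values to mean 0 and sample standard
#' deviation 1 (divisor n - 1) across that subject's own edges. This is the
#' default site-effect reduction step: each connectome is rescaled relative
#' to itself, so site-wide additive offsets in overall connectivity strength
#' are removed.
#'
#' @param edges Numeric vector of one subject's edge values (>= 2 distinct
#'   values).
#' @return Numeric vector of the same length and names.
#' @export
#' @examples
#' zscore_subject(c(1, 2, 3))
zscore_subject <- function(edges) {
  if (!is.numeric(edges) || length(edges) < 2) abort("need >= 2 edge values")
  s <- sd(edges)
  if (s == 0) abort("degenerate connectome: all edge values identical")
  (edges - mean(edges)) / s
}

#' Build a feature table from per-subject ROI time series
#'
#' Maps [pearson_fc()] + [vectorize_upper()] over a named list of time-series
#' tables and stacks the edge vectors into a subjects x edges tibble with a
#' `subject_id` column and canonical edge-name headers.
#'
#' @param series_list Named list of T x R matrices/data frames (names =
#'   subject ids), or a list of lists with `subject_id` and `data` entries.
#' @param strict Passed to [pearson_fc()].
#' @return A tibble: `subject_id` plus one column per edge.
#' @export
build_feature_table <- function(series_list, strict = FALSE) {
  if (!is.list(series_list) || length(series_list) == 0) {
    abort("series_list must be a non-empty list")
  }
  ids <- names(series_list)
  if (is.null(ids) || any(ids == "")) {
    if (all(vapply(series_list, function(s) is.list(s) && !is.null(s$subject_id),
                   logical(1)))) {
      ids <- vapply(series_list, function(s) as.character(s$subject_id), character(1))
      series_list <- lapply(series_list, function(s) s$data)
    } else {
      abort("series_list must be named by subject id")
    }
  }
  if (anyDuplicated(ids)) abort("duplicated subject ids in series_list")
  rows <- lapply(series_list, function(s) vectorize_upper(pearson_fc(s, strict = strict)))
  lens <- vapply(rows, length, integer(1))
  if (length(unique(lens)) != 1) abort("subjects have differing region counts")
  x <- do.call(rbind, rows)
  rownames(x) <- ids
  feature_tibble(x)
}

#' Apply per-subject Z-scoring to a whole feature table
#'
#' @param features Feature tibble (`subject_id` + edge columns).
#' @return Feature tibble of the same shape, each row standardized by
#'   [zscore_subject()].
#' @export
harmonize_zscore <- function(features) {
  x <- feature_matrix(features)
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  if (any(s == 0)) {
    abort(paste0("degenerate connectome (constant edges) for subject(s): ",
                 paste(rownames(x)[s == 0], collapse = ", ")))
  }
  feature_tibble((x - mu) / s)
}

#' Per-site, per-feature standardization
#'
#' Alternative reading of Z-score harmonization: each edge is standardized
#' to mean 0 / SD 1 within each acquisition site (divisor n - 1). Unlike
#' [harmonize_zscore()] this removes per-(site, edge) location and scale
#' differences but also absorbs any between-site biological differences.
#'
#' @param features Feature tibble aligned with `phenotypes`.
#' @param phenotypes Phenotype tibble with `subject_id` and `site` columns.
#' @return Feature tibble of the same shape.
#' @export
harmonize_zscore_site <- function(features, phenotypes) {
  check_alignment(features, phenotypes)
  x <- feature_matrix(features)
  site <- as.character(phenotypes[["site"]])
  for (s in unique(site)) {
    idx <- which(site == s)
    if (length(idx) < 2) abort(sprintf("site %s has < 2 subjects", s))
    xs <- x[idx, , drop = FALSE]
    mu <- colMeans(xs)
    sdev <- apply(xs, 2, sd)
    sdev[sdev == 0] <- 1
    x[idx, ] <- sweep(sweep(xs, 2, mu, "-"), 2, sdev, "/")
  }
  feature_tibble(x)
}
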