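# Internal helpers shared across modules.

# Canonical edge ordering: strictly upper triangle, row-major, i < j
# (0-based indices internally; names use 1-based zero-padded ROI labels).
edge_index_pairs <- function(n_regions) {
  stopifnot(n_regions >= 2)
  i <- rep.int(seq_len(n_regions - 1L), times = (n_regions - 1L):1L)
  j <- unlist(lapply(seq_len(n_regions - 1L), function(k) (k + 1L):n_regions),
              use.names = FALSE)
  cbind(i = i, j = j)
}

#' Canonical edge names for an R-region connectome
#'
#' Names follow the row-major strictly-upper-triangular ordering used by
#' [vectorize_upper()]: `"ROI001-ROI002"`, `"ROI001-ROI003"`, ...,
#' `"ROI115-ROI116"` for 116 regions.
#'
#' @param n_regions Number of regions (>= 2).
#' @param labels Optional character vector of region labels; defaults to
#'   zero-padded `ROI###` labels.
#' @return Character vector of length `n_regions * (n_regions - 1) / 2`.
#' @export
#' @examples
#' edge_names(4)
edge_names <- function(n_regions, labels = NULL) {
  if (is.null(labels)) {
    width <- max(3L, nchar(as.character(n_regions)))
    labels <- sprintf(paste0("ROI%0", width, "d"), seq_len(n_regions))
  }
  stopifnot(length(labels) == n_regions)
  pairs <- edge_index_pairs(n_regions)
  paste0(labels[pairs[, "i"]], "-", labels[pairs[, "j"]])
}

n_edges_for <- function(n_regions) n_regions * (n_regions - 1L) / 2L

# Inverse of n_edges_for; NA when no integer R matches.
regions_for_edges <- function(n_edges) {
  r <- (1 + sqrt(1 + 8 * n_edges)) / 2
  if (abs(r - round(r)) > 1e-9) return(NA_integer_)
  as.integer(round(r))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Convert a feature table (tibble: subject_id + edge columns) to a plain
# numeric matrix with subject ids as rownames. Validates shape.
feature_matrix <- function(features) {
  stopifnot(is.data.frame(features), "subject_id" %in% names(features))
  ids <- as.character(features[["subject_id"]])
  if (anyDuplicated(ids)) {
    abort("duplicated subject_id in feature table")
  }
  x <- as.matrix(features[setdiff(names(features), "subject_id")])
  if (!is.numeric(x)) abort("feature columns must be numeric")
  rownames(x) <- ids
  x
}

# Back to the tibble form.
feature_tibble <- function(x) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  out <- tibble::as_tibble(x, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(subject_id = rownames(x)), out)
}

# Check phenotype/feature row alignment by subject_id.
check_alignment <- function(features, phenotypes) {
  fid <- as.character(features[["subject_id"]])
  pid <- as.character(phenotypes[["subject_id"]])
  if (length(fid) != length(pid) || !all(fid == pid)) {
    abort("feature table and phenotype table rows are not aligned by subject_id")
  }
  invisible(TRUE)
}

# Age-decile stratum labels (deciles of the supplied ages themselves).
age_decile <- function(age) {
  br <- unique(quantile(age, probs = seq(0, 1, 0.1), names = FALSE))
  if (length(br) < 2) return(rep(1L, length(age)))
  as.integer(cut(age, breaks = br, include.lowest = TRUE))
}

# Round all numerics in a nested list to `digits` significant digits; used
# for the canonical (byte-stable) serialization of run summaries.
round_sig <- function(x, digits = 8) {
  if (is.list(x)) return(lapply(x, round_sig, digits = digits))
  if (is.numeric(x)) return(signif(x, digits))
  x
}
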