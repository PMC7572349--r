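#' Edge index map: fixed bijection between vector positions and ROI pairs
#'
#' Row-major strict upper triangle: position p holds pair (i, j) with i < j,
#' enumerated as (1,2), (1,3), ..., (1,n), (2,3), ...  This single ordering
#' is used for every vectorized CMN, ranking and report in the package.
#'
#' @param rois Either an integer ROI count or a character vector of region
#'   names (order defines the indexing).
#' @return data.frame with columns `i`, `j` (1-based ROI indices) and `name`
#'   (`"roiA|roiB"`), with `n_r * (n_r - 1) / 2` rows.
#' @export
#' @examples
#' nrow(edge_index_map(35))  # 595
edge_index_map <- function(rois) {
  if (is.character(rois)) {
    roi_names <- rois
    n <- length(rois)
  } else {
    if (!is_count(rois, 2)) stopf("rois must be >= 2")
    n <- as.integer(rois)
    roi_names <- .roi_names(n)
  }
  if (anyDuplicated(roi_names)) stopf("ROI names must be unique")
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  data.frame(i = i, j = j,
             name = paste(roi_names[i], roi_names[j], sep = "|"),
             stringsAsFactors = FALSE)
}

#' Average per-vertex attribute values into per-ROI means
#'
#' @param vertex_values Numeric vector (one subject) or subjects x vertices
#'   matrix of per-vertex attribute values.
#' @param assignment Integer vector mapping each vertex to a 1-based ROI
#'   index, or a character vector of ROI names.
#' @param roi_names Optional region names; every ROI must receive at least
#'   one vertex, otherwise an error names the empty region.
#' @return Per-ROI mean vector (or subjects x n_rois matrix).
#' @export
average_roi_measurement <- function(vertex_values, assignment,
                                    roi_names = NULL) {
  one_dim <- is.null(dim(vertex_values))
  X <- if (one_dim) matrix(vertex_values, nrow = 1) else as.matrix(vertex_values)
  if (length(assignment) != ncol(X))
    stopf("assignment length (%d) must match vertex count (%d)",
          length(assignment), ncol(X))
  if (is.character(assignment)) {
    if (is.null(roi_names)) roi_names <- unique(assignment)
    assignment <- match(assignment, roi_names)
    if (anyNA(assignment)) stopf("assignment contains unknown ROI names")
  }
  n_r <- if (is.null(roi_names)) max(assignment) else length(roi_names)
  if (is.null(roi_names)) roi_names <- .roi_names(n_r)
  counts <- tabulate(assignment, nbins = n_r)
  if (any(counts == 0))
    stopf("ROI(s) with zero assigned vertices: %s",
          paste(roi_names[counts == 0], collapse = ", "))
  sums <- t(rowsum(t(X), group = factor(assignment, levels = seq_len(n_r))))
  out <- sweep(sums, 2, counts, "/")
  colnames(out) <- roi_names
  if (one_dim) out[1, ] else out
}

#' Build a cortical morphological network from per-ROI means
#'
#' The CMN entry for ROIs i and j is the absolute difference of their
#' ROI-averaged measurement, `|m_i - m_j|`: as two regions become similar in
#' morphology their connection weight tends to 0.  The result is symmetric,
#' nonnegative, with an exactly zero diagonal.
#'
#' @param roi_means Finite numeric vector of per-ROI means (optionally
#'   named).
#' @return n_r x n_r matrix of morphological distances.
#' @export
build_cmn <- function(roi_means) {
  if (!is.numeric(roi_means) || length(roi_means) < 2)
    stopf("roi_means must be a numeric vector of length >= 2")
  if (any(!is.finite(roi_means))) stopf("roi_means must be finite")
  m <- abs(outer(roi_means, roi_means, "-"))
  diag(m) <- 0
  if (!is.null(names(roi_means)))
    dimnames(m) <- list(names(roi_means), names(roi_means))
  m
}

.validate_cmn <- function(cmn, tol = 1e-8) {
  if (!is.matrix(cmn) || nrow(cmn) != ncol(cmn))
    stopf("a CMN must be a square matrix")
  if (any(!is.finite(cmn))) stopf("CMN contains non-finite entries")
  if (max(abs(cmn - t(cmn))) > tol) stopf("CMN must be symmetric")
  if (any(abs(diag(cmn)) > tol)) stopf("CMN must have a zero diagonal")
  if (any(cmn < -tol)) stopf("CMN entries must be nonnegative")
  invisible(cmn)
}

#' Vectorize / devectorize a CMN
#'
#' `vectorize_cmn()` extracts the strict upper triangle of a valid CMN in the
#' fixed row-major order of [edge_index_map()]; `devectorize_cmn()` inverts
#' it exactly.
#'
#' @param cmn A symmetric nonnegative zero-diagonal matrix.
#' @param map Optional [edge_index_map()] (defaults to the map for
#'   `nrow(cmn)`, using row names when present).
#' @return Named numeric vector of length `n_r * (n_r - 1) / 2`.
#' @export
vectorize_cmn <- function(cmn, map = NULL) {
  .validate_cmn(cmn)
  if (is.null(map))
    map <- edge_index_map(if (is.null(rownames(cmn))) nrow(cmn)
                          else rownames(cmn))
  v <- cmn[cbind(map$i, map$j)]
  names(v) <- map$name
  v
}

#' @param x Feature vector as produced by `vectorize_cmn()`.
#' @param rois ROI count or names (must match the vector length).
#' @rdname vectorize_cmn
#' @export
devectorize_cmn <- function(x, rois) {
  map <- edge_index_map(rois)
  if (length(x) != nrow(map))
    stopf("vector length %d does not match %d edges", length(x), nrow(map))
  n <- max(map$j)
  m <- matrix(0, n, n)
  m[cbind(map$i, map$j)] <- x
  m <- m + t(m)
  roi_names <- if (is.character(rois)) rois else .roi_names(n)
  dimnames(m) <- list(roi_names, roi_names)
  m
}

#' Build the cohort feature table of vectorized CMNs
#'
#' Row s is the vectorized CMN of subject s: `|values[s, i] - values[s, j]|`
#' for every ROI pair (i, j) in [edge_index_map()] order.
#'
#' @param values Subjects x n_rois matrix of ROI-level values, or a
#'   `cmn_attribute_table`.
#' @return Subjects x n_f feature matrix with `"roiA|roiB"` column names.
#' @export
build_feature_table <- function(values) {
  if (inherits(values, "cmn_attribute_table")) values <- values$values
  if (!is.matrix(values) || ncol(values) < 2)
    stopf("values must be a subjects x n_rois matrix (n_rois >= 2)")
  if (any(!is.finite(values))) stopf("values must be finite (no missing)")
  map <- edge_index_map(if (is.null(colnames(values))) ncol(values)
                        else colnames(values))
  X <- abs(values[, map$i, drop = FALSE] - values[, map$j, drop = FALSE])
  colnames(X) <- map$name
  rownames(X) <- rownames(values)
  X
}
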