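#' Parameters for infinite feature selection
#'
#' The feature-graph adjacency mixes a dispersion term and a decorrelation
#' term, `A(k,l) = alpha * max(sd_k, sd_l) + (1 - alpha) *
#' (1 - |spearman(f_k, f_l)|)`, and features are scored by summing weighted
#' walks of every length through the graph, `S = (I - r A)^{-1} - I`,
#' `scores = S e`.
#'
#' `standardize = FALSE` (the default) keeps feature standard deviations on
#' their raw attribute scale: this is the only channel through which a group
#' mean difference (which inflates the pooled variance of affected
#' connections) can raise a feature's score, since the formulas contain no
#' label term.  With `standardize = TRUE` features are z-scored first, every
#' `sd_k` is 1 and ranking is driven purely by decorrelation; that mode
#' bounds the adjacency entries and helps convergence for large feature
#' counts, but is blind to group structure (see the methods vignette).
#'
#' @param alpha Loading coefficient in `[0, 1]` mixing dispersion vs
#'   decorrelation (default 0.5; the method only requires `alpha` in
#'   `[0, 1]`).
#' @param r Regularization factor damping the walk-length series (default
#'   0.01); the closed form requires spectral radius `rho(r A) < 1`.
#' @param standardize Z-score features before computing the adjacency.
#' @return An object of class `cmn_infs_params`.
#' @export
infs_params <- function(alpha = 0.5, r = 0.01, standardize = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stopf("alpha must be a scalar in [0, 1]")
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r <= 0)
    stopf("r must be a positive scalar")
  structure(list(alpha = alpha, r = r,
                 standardize = isTRUE(standardize)),
            class = "cmn_infs_params")
}

#' Feature-graph adjacency for infinite feature selection
#'
#' @param features Subjects x n_f numeric matrix (>= 3 subjects, >= 2
#'   features).
#' @param params An [infs_params()] object.
#' @return Symmetric n_f x n_f adjacency.  Constant features (zero sd) get
#'   `c_kl = 1` (treated as uncorrelated) and contribute `sd = 0`; they are
#'   reported via a warning.
#' @export
feature_adjacency <- function(features, params = infs_params()) {
  if (!inherits(params, "cmn_infs_params"))
    stopf("params must be created by infs_params()")
  X <- as.matrix(features)
  if (nrow(X) < 3)
    stopf("need at least 3 subjects for a Spearman-based adjacency")
  if (ncol(X) < 2) stopf("need at least 2 features")
  if (any(!is.finite(X))) stopf("features must be finite")

  sds <- apply(X, 2, sd)
  const <- sds == 0
  if (params$standardize) {
    X <- sweep(X, 2, colMeans(X), "-")
    X[, !const] <- sweep(X[, !const, drop = FALSE], 2, sds[!const], "/")
    sds <- ifelse(const, 0, 1)
  }
  if (any(const))
    warnf("%d constant feature(s) treated as uncorrelated (c_kl = 1)",
          sum(const))

  ranks <- apply(X, 2, rank)           # tie-corrected Spearman via Pearson
  rho <- suppressWarnings(cor(ranks))  # NA for constant features
  rho[is.na(rho)] <- 0
  ckl <- 1 - abs(rho)
  diag(ckl) <- 0                       # Spearman(f, f) = 1
  A <- params$alpha * outer(sds, sds, pmax) + (1 - params$alpha) * ckl
  dimnames(A) <- list(colnames(features), colnames(features))
  A
}

#' Infinite feature selection relevance scores
#'
#' Closed form of the infinite walk-sum: `S = (I - r A)^{-1} - I`, score of
#' feature i is the i-th row sum `[S e]_i`, equal to the convergent Neumann
#' series `sum_{p >= 1} r^p (A^p e)_i`.
#'
#' @param A Symmetric nonnegative adjacency from [feature_adjacency()] (a
#'   single scalar is accepted as a 1 x 1 matrix).
#' @param r Regularization factor; `rho(r A) < 1` is checked and violation
#'   raises an error suggesting a smaller `r` or standardization (the series
#'   diverges; the score is undefined, never silently regularized).
#' @return Numeric score vector.
#' @export
infs_scores <- function(A, r = 0.01) {
  if (!is.matrix(A)) A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stopf("A must be square")
  if (any(!is.finite(A))) stopf("A must be finite")
  if (max(abs(A - t(A))) > 1e-8) stopf("A must be symmetric")
  p <- nrow(A)
  # cheap Gershgorin-type bound first; exact spectral radius only if needed
  if (r * max(rowSums(abs(A))) >= 1) {
    rho <- max(abs(eigen(A, symmetric = TRUE,
                         only.values = TRUE)$values))
    if (r * rho >= 1)
      stopf(paste("spectral radius of r*A is %.4f >= 1: the walk series",
                  "diverges; lower r or standardize features"), r * rho)
  }
  S <- solve(diag(p) - r * A)
  scores <- rowSums(S) - 1           # (S - I) e
  names(scores) <- rownames(A)
  scores
}

#' Rank features by relevance score
#'
#' Deterministic non-increasing score order; ties broken by ascending
#' feature index.
#'
#' @param scores Finite numeric score vector.
#' @param params Optional [infs_params()] recorded alongside the ranking.
#' @return Object of class `cmn_feature_ranking` with `scores`, `ranks`
#'   (permutation of feature indices, best first) and `params`.
#' @export
rank_features <- function(scores, params = NULL) {
  if (any(!is.finite(scores))) stopf("scores must be finite")
  ranks <- order(-scores, seq_along(scores))
  structure(list(scores = scores, ranks = ranks, params = params),
            class = "cmn_feature_ranking")
}

#' @export
print.cmn_feature_ranking <- function(x, n = 5, ...) {
  cat(sprintf("cmn_feature_ranking: %d features, top %d:\n",
              length(x$scores), min(n, length(x$scores))))
  top <- x$ranks[seq_len(min(n, length(x$scores)))]
  nm <- names(x$scores)[top] %||% as.character(top)
  print(data.frame(feature = nm, score = unname(x$scores[top])))
  invisible(x)
}

#' One-call infinite feature selection
#'
#' Builds the adjacency, scores and ranks features.
#'
#' @inheritParams feature_adjacency
#' @return A `cmn_feature_ranking`.
#' @export
infs_select <- function(features, params = infs_params()) {
  A <- feature_adjacency(features, params)
  rank_features(infs_scores(A, params$r), params)
}

#' Write a feature ranking as CSV (edge_name, score, rank)
#'
#' @param ranking A `cmn_feature_ranking`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ranking_csv <- function(ranking, path) {
  nm <- names(ranking$scores) %||% as.character(seq_along(ranking$scores))
  pos <- integer(length(ranking$ranks))
  pos[ranking$ranks] <- seq_along(ranking$ranks)
  df <- data.frame(edge_name = nm, score = unname(ranking$scores),
                   rank = pos)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
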