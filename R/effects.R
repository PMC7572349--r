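#' Cohen's d for one connection between two groups
#'
#' As the standardized difference `d = |mean(a) - mean(b)| / stdm` with
#' `stdm = (sd(a) + sd(b)) / 2`, using sample (n-1) standard deviations.
#' The statistic is nonnegative and — despite a common informal reading —
#' not bounded by 1; values are reported as computed, never clipped.
#'
#' @param values_a,values_b Connection values in each group (>= 2 each).
#' @return List of class `cmn_edge_effect`: `mu_a`, `mu_b`, `sigma_a`,
#'   `sigma_b`, `d`.  Both sds zero with equal means gives `d = 0`; with
#'   unequal means the statistic is undefined and an error is raised.
#' @export
cohens_d <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stopf("need at least 2 values per group")
  if (any(!is.finite(values_a)) || any(!is.finite(values_b)))
    stopf("values must be finite")
  mu_a <- mean(values_a); mu_b <- mean(values_b)
  s_a <- sd(values_a); s_b <- sd(values_b)
  stdm <- (s_a + s_b) / 2
  if (stdm == 0) {
    if (mu_a == mu_b) d <- 0
    else stopf("both group sds are zero with unequal means: d is undefined")
  } else d <- abs(mu_a - mu_b) / stdm
  structure(list(mu_a = mu_a, mu_b = mu_b, sigma_a = s_a, sigma_b = s_b,
                 d = d), class = "cmn_edge_effect")
}

#' Effect-size band per Cohen's conventional thresholds
#'
#' `d >= 0.8` large, `>= 0.5` medium, `>= 0.2` small, otherwise `n.s.`;
#' band boundaries are exactly these constants.
#'
#' @param d Numeric vector of effect sizes.
#' @return Character vector of bands.
#' @export
effect_band <- function(d) {
  as.character(cut(d, breaks = c(-Inf, 0.2, 0.5, 0.8, Inf),
                   labels = c("n.s.", "small", "medium", "large"),
                   right = FALSE))
}

#' Cohen's d table for a set of connections
#'
#' Computes the effect size of each requested edge on all subjects (no
#' cross-validation), sorted by decreasing d.
#'
#' @param features Subjects x n_f feature matrix (columns named
#'   `"roiA|roiB"`).
#' @param labels Two-level group labels; the first level is group a.
#' @param edges Edge selection: integer feature indices or edge names
#'   (default: all columns).
#' @param sort Sort by decreasing d (default TRUE).
#' @return data.frame with `edge_name`, `roi_a`, `roi_b`, group means/sds,
#'   `d` and `band`.
#' @export
effect_table <- function(features, labels, edges = NULL, sort = TRUE) {
  features <- as.matrix(features)
  if (!is.factor(labels)) labels <- factor(labels)
  if (nlevels(labels) != 2) stopf("labels must have exactly two classes")
  if (is.null(edges)) edges <- seq_len(ncol(features))
  if (is.character(edges)) {
    idx <- match(edges, colnames(features))
    if (anyNA(idx))
      stopf("unknown edge name(s): %s",
            paste(edges[is.na(idx)], collapse = ", "))
    edges <- idx
  }
  if (any(edges < 1 | edges > ncol(features)))
    stopf("edge indices out of range 1..%d", ncol(features))
  a <- labels == levels(labels)[1]
  rows <- lapply(edges, function(e) {
    eff <- cohens_d(features[a, e], features[!a, e])
    nm <- colnames(features)[e] %||% as.character(e)
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    data.frame(edge_name = nm,
               roi_a = parts[1],
               roi_b = if (length(parts) > 1) parts[2] else NA_character_,
               mu_a = eff$mu_a, mu_b = eff$mu_b,
               sigma_a = eff$sigma_a, sigma_b = eff$sigma_b,
               d = eff$d, band = effect_band(eff$d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (sort) out <- out[order(-out$d, seq_len(nrow(out))), ]
  rownames(out) <- NULL
  out
}
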