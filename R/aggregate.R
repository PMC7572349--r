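#' Aggregate top features across cross-validation schemes
#'
#' For one measurement/hemisphere, takes the per-scheme weight vectors and
#' top-`k_f` sets and averages them over schemes on the union of the top
#' sets: an edge absent from a scheme's top set contributes 0 for that
#' scheme, so non-reproducible edges are penalized.  Because inFS score
#' magnitudes vary with fold size, each scheme's weights are min-max
#' normalized to `[0, 1]` before averaging (disable with
#' `normalize = FALSE` for raw-scale averaging).
#'
#' @param rankings List of [scheme_ranking()] objects for the same
#'   measurement and hemisphere (typically LOO, 5-fold and 10-fold).
#' @param normalize Min-max normalize each scheme's weights first (default
#'   TRUE).
#' @return Object of class `cmn_edge_weights`: data.frame `edges` with
#'   `edge` (feature index), `edge_name`, `weight`, sorted by decreasing
#'   weight, plus context fields.  The union size `k_f'` satisfies
#'   `k_f <= k_f' <= n_schemes * k_f`.
#' @export
aggregate_schemes <- function(rankings, normalize = TRUE) {
  if (!length(rankings)) stopf("no rankings supplied")
  if (!all(vapply(rankings, inherits, logical(1), "cmn_scheme_ranking")))
    stopf("rankings must be scheme_ranking() objects")
  meas <- unique(vapply(rankings, function(r) r$measurement %||% "",
                        character(1)))
  hemi <- unique(vapply(rankings, function(r) r$hemisphere %||% "",
                        character(1)))
  if (length(meas) != 1 || length(hemi) != 1)
    stopf("all rankings must share one measurement/hemisphere context")
  kfs <- unique(vapply(rankings, function(r) r$k_f, integer(1)))
  if (length(kfs) != 1) stopf("all rankings must use the same k_f")
  nf <- unique(vapply(rankings, function(r) r$n_features, integer(1)))
  if (length(nf) != 1) stopf("rankings disagree on the feature count")

  union_edges <- sort(unique(unlist(lapply(rankings, `[[`, "top_set"))))
  contrib <- vapply(rankings, function(r) {
    w <- r$weights
    if (normalize) {
      rng <- range(w)
      w <- if (rng[2] > rng[1]) (w - rng[1]) / (rng[2] - rng[1])
           else rep(0, length(w))
    }
    names(w) <- as.character(r$columns)
    out <- numeric(length(union_edges))
    in_top <- union_edges %in% r$top_set
    out[in_top] <- w[as.character(union_edges[in_top])]
    out
  }, numeric(length(union_edges)))
  contrib <- matrix(contrib, nrow = length(union_edges))
  weight <- rowMeans(contrib)
  nm <- names(rankings[[1]]$weights)
  edge_name <- if (!is.null(nm)) {
    nm[match(union_edges, rankings[[1]]$columns)]
  } else as.character(union_edges)
  ord <- order(-weight, union_edges)
  edges <- data.frame(edge = union_edges, edge_name = edge_name,
                      weight = weight, stringsAsFactors = FALSE)[ord, ]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 measurement = if (nzchar(meas)) meas else NULL,
                 hemisphere = if (nzchar(hemi)) hemi else NULL,
                 k_f = kfs, n_features = nf,
                 n_schemes = length(rankings)),
            class = "cmn_edge_weights")
}

#' Aggregate edge weights across measurements into the final top set
#'
#' Per-edge mean of the cross-scheme-averaged weights across measurements
#' (an edge absent from a measurement's union contributes 0), then the top
#' `k_f` edges by averaged weight, ties broken by ascending edge index.
#'
#' @param per_measurement List of [aggregate_schemes()] results (one per
#'   measurement, same hemisphere).
#' @param k_f Final top-set size (default 5).
#' @param roi_names Optional region names used to attach `roi_a` / `roi_b`
#'   columns.
#' @return Object of class `cmn_final_edges`: data.frame `edges` with
#'   `rank`, `edge`, `edge_name`, `roi_a`, `roi_b`, one weight column per
#'   measurement and `weight` (the cross-measurement mean).
#' @export
aggregate_measurements <- function(per_measurement, k_f = 5L,
                                   roi_names = NULL) {
  if (!length(per_measurement)) stopf("no measurements supplied")
  if (!all(vapply(per_measurement, inherits, logical(1),
                  "cmn_edge_weights")))
    stopf("per_measurement must be aggregate_schemes() results")
  hemi <- unique(vapply(per_measurement,
                        function(x) x$hemisphere %||% "", character(1)))
  if (length(hemi) != 1)
    stopf("all measurements must belong to one hemisphere")
  nf <- unique(vapply(per_measurement, function(x) x$n_features,
                      integer(1)))
  if (length(nf) != 1) stopf("measurements disagree on the feature count")
  if (!is_count(k_f, 1) || k_f > nf)
    stopf("k_f must be a positive integer <= n_f (%d)", nf)

  meas <- vapply(per_measurement,
                 function(x) x$measurement %||% "measurement",
                 character(1))
  if (anyDuplicated(meas)) stopf("duplicate measurement contexts")
  names(per_measurement) <- meas

  all_edges <- sort(unique(unlist(lapply(per_measurement,
                                         function(x) x$edges$edge))))
  W <- vapply(per_measurement, function(x) {
    out <- numeric(length(all_edges))
    out[match(x$edges$edge, all_edges)] <- x$edges$weight
    out
  }, numeric(length(all_edges)))
  W <- matrix(W, nrow = length(all_edges),
              dimnames = list(NULL, meas))
  weight <- rowMeans(W)
  ord <- order(-weight, all_edges)
  take <- ord[seq_len(min(k_f, length(all_edges)))]

  name_lookup <- do.call(rbind, lapply(per_measurement, function(x)
    x$edges[c("edge", "edge_name")]))
  edge_name <- name_lookup$edge_name[match(all_edges[take],
                                           name_lookup$edge)]
  edges <- data.frame(rank = seq_along(take), edge = all_edges[take],
                      edge_name = edge_name, stringsAsFactors = FALSE)
  if (!is.null(roi_names)) {
    map <- edge_index_map(roi_names)
    edges$roi_a <- roi_names[map$i[edges$edge]]
    edges$roi_b <- roi_names[map$j[edges$edge]]
  } else {
    parts <- strsplit(edges$edge_name, "|", fixed = TRUE)
    edges$roi_a <- vapply(parts, `[`, character(1), 1)
    edges$roi_b <- vapply(parts, function(p)
      if (length(p) > 1) p[2] else NA_character_, character(1))
  }
  for (m in meas) edges[[paste0("w_", m)]] <- W[take, m]
  edges$weight <- weight[take]
  structure(list(edges = edges, hemisphere =
                   if (nzchar(hemi)) hemi else NULL,
                 k_f = as.integer(k_f), measurements = meas,
                 n_features = nf),
            class = "cmn_final_edges")
}

#' @export
print.cmn_final_edges <- function(x, ...) {
  cat(sprintf("cmn_final_edges%s: top %d connections over %d measurement(s)\n",
              if (is.null(x$hemisphere)) "" else paste0(" [", x$hemisphere, "]"),
              nrow(x$edges), length(x$measurements)))
  print(x$edges[c("rank", "edge_name", "weight")])
  invisible(x)
}

#' Full reproducibility report for one hemisphere
#'
#' Runs the per-scheme ranking for every measurement, aggregates across
#' schemes and measurements, and attaches Cohen's d per final edge (computed
#' per measurement on the full cohort, plus their mean).
#'
#' @param feature_tables Named list (by measurement) of subjects x n_f
#'   feature matrices for one hemisphere.
#' @param labels Two-level group labels.
#' @param schemes List of [cv_scheme()] objects (default LOO, 5-fold,
#'   10-fold).
#' @param params [infs_params()].
#' @param k_f Top-set size per scheme and finally (default 5).
#' @param hemisphere Context label.
#' @param normalize Passed to [aggregate_schemes()].
#' @return Object of class `cmn_reproducibility_report` with
#'   `per_measurement` (cross-scheme unions), `final` (a
#'   `cmn_final_edges`), and `effects` (Cohen's d table for the final
#'   edges).
#' @export
reproducibility_report <- function(feature_tables, labels,
                                   schemes = default_schemes(),
                                   params = infs_params(), k_f = 5L,
                                   hemisphere = NULL, normalize = TRUE) {
  if (is.null(names(feature_tables)))
    stopf("feature_tables must be a named list (by measurement)")
  per_meas <- lapply(names(feature_tables), function(m) {
    X <- feature_tables[[m]]
    rks <- lapply(schemes, function(s)
      scheme_ranking(X, labels, s, params, k_f = k_f, measurement = m,
                     hemisphere = hemisphere))
    aggregate_schemes(rks, normalize = normalize)
  })
  final <- aggregate_measurements(per_meas, k_f = k_f)

  eff <- do.call(rbind, lapply(names(feature_tables), function(m) {
    tab <- effect_table(feature_tables[[m]], labels,
                        edges = final$edges$edge, sort = FALSE)
    tab$measurement <- m
    tab
  }))
  d_mat <- matrix(eff$d, nrow = nrow(final$edges),
                  dimnames = list(NULL, names(feature_tables)))
  final$edges$cohens_d <- rowMeans(d_mat)
  structure(list(per_measurement = per_meas, final = final, effects = eff,
                 hemisphere = hemisphere, k_f = as.integer(k_f)),
            class = "cmn_reproducibility_report")
}

#' Default cross-validation scheme set (LOO, 5-fold, 10-fold)
#'
#' @param seed Base seed; each scheme gets a distinct derived seed.
#' @param stratified Passed to [cv_scheme()].
#' @return List of three `cmn_cv_scheme` objects.
#' @export
default_schemes <- function(seed = 42L, stratified = TRUE) {
  list(cv_scheme("loo", seed = seed, stratified = stratified),
       cv_scheme("kfold", n_folds = 5L, seed = seed + 1L,
                 stratified = stratified),
       cv_scheme("kfold", n_folds = 10L, seed = seed + 2L,
                 stratified = stratified))
}

#' Write a reproducibility report as CSV and a plain edge list
#'
#' @param report A `cmn_reproducibility_report`.
#' @param csv_path Destination for the ranked table (rank, roi_a, roi_b,
#'   per-measurement weights, averaged weight, cohens_d).
#' @param edgelist_path Optional plain two-column edge list consumable by
#'   circular-graph tools.
#' @return `csv_path`, invisibly.
#' @export
write_report_csv <- function(report, csv_path, edgelist_path = NULL) {
  df <- report$final$edges
  write.csv(df[setdiff(names(df), "edge")], csv_path, row.names = FALSE,
            quote = FALSE)
  if (!is.null(edgelist_path))
    writeLines(paste(df$roi_a, df$roi_b, sep = "\t"), edgelist_path)
  invisible(csv_path)
}

#' Minimal circular plot of the top connections
#'
#' Convenience plot: ROIs on a circle, top edges drawn with width
#' proportional to their aggregated weight.  Not a publication-grade
#' circular graph.
#'
#' @param final A `cmn_final_edges` (or a report containing one).
#' @param roi_names Region names defining the circle order.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted edge table.
#' @export
plot_top_edges <- function(final, roi_names, ...) {
  if (inherits(final, "cmn_reproducibility_report")) final <- final$final
  n <- length(roi_names)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  xs <- cos(theta); ys <- sin(theta)
  graphics::plot(xs, ys, asp = 1, axes = FALSE, xlab = "", ylab = "",
                 pch = 19, cex = 0.6,
                 xlim = c(-1.35, 1.35), ylim = c(-1.35, 1.35), ...)
  graphics::text(1.22 * xs, 1.22 * ys, roi_names, cex = 0.55,
                 srt = 0, xpd = NA)
  ed <- final$edges
  map <- edge_index_map(roi_names)
  w <- ed$weight / max(ed$weight)
  for (k in seq_len(nrow(ed))) {
    i <- map$i[ed$edge[k]]; j <- map$j[ed$edge[k]]
    graphics::segments(xs[i], ys[i], xs[j], ys[j], lwd = 0.5 + 3 * w[k],
                       col = grDevices::adjustcolor("firebrick",
                                                    alpha.f = 0.8))
  }
  invisible(ed)
}
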