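# Shared fixtures and independent oracles, built in code at test time.

# Small one-hemisphere cohort builder.
quick_cohort <- function(n_a = 30, n_b = 30, n_rois = 10,
                         measurements = "cortical_thickness",
                         effects = NULL, seed = 1, vertices = NULL) {
  cfg <- synthetic_config(n_a, n_b, n_rois, measurements = measurements,
                          injected_effects = effects, hemispheres = "lh",
                          vertices_per_roi = vertices, seed = seed)
  simulate_cohort(cfg)
}

# Opposed-shift effect rows targeting edge (roi_i, roi_j): +delta/2 on roi_i,
# -delta/2 on roi_j in group B, per measurement.
opposed_effect <- function(measurements, roi_i, roi_j, delta) {
  do.call(rbind, lapply(seq_along(measurements), function(k)
    data.frame(measurement = measurements[k],
               roi_index = c(roi_i, roi_j), group = "B",
               mean_shift = c(delta[k] / 2, -delta[k] / 2))))
}

# Solve the opposed-shift delta giving a target theoretical d on edge
# (roi_i, roi_j) for one measurement (baselines at package defaults).
delta_for_target_d <- function(measurement, target_d, roi_i = 2, roi_j = 5,
                               n_rois = 15, n_a = 100, n_b = 100) {
  f <- function(delta) {
    cfg <- synthetic_config(n_a, n_b, n_rois, measurements = measurement,
                            injected_effects = opposed_effect(measurement,
                                                              roi_i, roi_j,
                                                              delta),
                            hemispheres = "lh", seed = 1)
    expected_connection_effect(cfg, measurement, roi_i, roi_j) - target_d
  }
  uniroot(f, c(1e-6, 20), tol = 1e-10)$root
}

# Independent truncated Neumann-series oracle for inFS scores.
series_scores <- function(A, r, terms = 100) {
  p <- nrow(A)
  acc <- numeric(p)
  v <- rep(1, p)
  for (k in seq_len(terms)) {
    v <- r * (A %*% v)
    acc <- acc + v
  }
  drop(acc)
}

# Naive tie-corrected Spearman correlation (rank + Pearson, written out).
spearman_ref <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Random valid CMN for algebra tests.
random_cmn <- function(n, seed = 1) {
  m <- withr::with_seed(seed, rnorm(n))
  names(m) <- sprintf("r%02d", seq_len(n))
  build_cmn(m)
}
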