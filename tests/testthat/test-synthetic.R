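test_that("config validation names the offending field", {
  expect_error(synthetic_config(n_group_a = 1), "n_group_a")
  expect_error(synthetic_config(baseline_sd = 0), "baseline_sd")
  expect_error(synthetic_config(baseline_sd = -0.1), "baseline_sd")
  expect_error(
    synthetic_config(injected_effects = data.frame(
      measurement = "cortical_thickness", roi_index = 99, group = "B",
      mean_shift = 1)),
    "roi_index")
  expect_error(
    synthetic_config(injected_effects = data.frame(
      measurement = "nope", roi_index = 1, group = "B", mean_shift = 1)),
    "measurement")
  expect_error(
    synthetic_config(injected_effects = data.frame(
      measurement = "cortical_thickness", roi_index = 1, group = "C",
      mean_shift = 1)),
    "group")
})

test_that("identical configs reproduce identical cohorts bit for bit", {
  co1 <- quick_cohort(seed = 11)
  co2 <- quick_cohort(seed = 11)
  expect_identical(co1$tables[[1]]$values, co2$tables[[1]]$values)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(co1, f1); write_cohort_csv(co2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
  co3 <- quick_cohort(seed = 12)
  expect_false(identical(co1$tables[[1]]$values, co3$tables[[1]]$values))
})

test_that("zero-shift injected effects give a no-effect cohort", {
  eff0 <- data.frame(measurement = "cortical_thickness", roi_index = 3,
                     group = "B", mean_shift = 0)
  expect_identical(quick_cohort(effects = eff0, seed = 5)$tables[[1]]$values,
                   quick_cohort(effects = NULL, seed = 5)$tables[[1]]$values)
})

test_that("an injected effect is local to the shifted ROI's connections", {
  eff <- data.frame(measurement = "cortical_thickness", roi_index = 4,
                    group = "B", mean_shift = 0.5)
  co_eff <- quick_cohort(effects = eff, seed = 8)
  co_null <- quick_cohort(effects = NULL, seed = 8)
  dv <- co_eff$tables[[1]]$values - co_null$tables[[1]]$values
  expect_true(all(dv[, -4] == 0))            # only ROI 4 changed
  X_eff <- build_feature_table(co_eff$tables[[1]])
  X_null <- build_feature_table(co_null$tables[[1]])
  map <- edge_index_map(10)
  incident <- map$i == 4 | map$j == 4
  expect_true(all(X_eff[, !incident] == X_null[, !incident]))
  expect_false(all(X_eff[, incident] == X_null[, incident]))
})

test_that("theoretical connection effect matches a Monte-Carlo oracle", {
  m <- "cortical_thickness"
  delta <- 0.45
  cfg <- synthetic_config(100, 100, 15, measurements = m,
                          injected_effects = opposed_effect(m, 2, 5, delta),
                          hemispheres = "lh", seed = 1)
  d_or <- expected_connection_effect(cfg, m, 2, 5)
  s <- sqrt(2) * 0.15
  d_mc <- withr::with_seed(99, {
    xa <- abs(rnorm(1e6, 0, s)); xb <- abs(rnorm(1e6, delta, s))
    abs(mean(xb) - mean(xa)) / ((sd(xa) + sd(xb)) / 2)
  })
  expect_lt(abs(d_or - d_mc), 0.01)
  # symmetry: shifting group A instead leaves d unchanged
  effA <- opposed_effect(m, 2, 5, delta); effA$group <- "A"
  cfgA <- synthetic_config(100, 100, 15, measurements = m,
                           injected_effects = effA, hemispheres = "lh",
                           seed = 1)
  expect_equal(expected_connection_effect(cfgA, m, 2, 5), d_or)
  # trivial cases and domain errors
  cfg0 <- synthetic_config(100, 100, 15, measurements = m,
                           hemispheres = "lh", seed = 1)
  expect_equal(expected_connection_effect(cfg0, m, 2, 5), 0)
  expect_error(expected_connection_effect(cfg, m, 3, 3), "distinct")
  expect_error(expected_connection_effect(cfg, "nope", 1, 2), "measurement")
})

test_that("empirical Cohen's d at large n matches the folded-normal oracle", {
  m <- "cortical_thickness"
  delta <- delta_for_target_d(m, 1.0, n_a = 5000, n_b = 5000)
  cfg <- synthetic_config(5000, 5000, 6, measurements = m,
                          injected_effects = opposed_effect(m, 2, 5, delta),
                          hemispheres = "lh", seed = 3)
  co <- simulate_cohort(cfg)
  X <- build_feature_table(co$tables[[1]])
  tab <- effect_table(X, co$labels, edges = "roi02|roi05")
  expect_lt(abs(tab$d - expected_connection_effect(cfg, m, 2, 5)), 0.05)
})

test_that("vertex-level generation averages to the sd/sqrt(V) ROI model", {
  co_v <- quick_cohort(n_a = 2000, n_b = 2000, n_rois = 4, seed = 21,
                       vertices = 4)
  sds <- apply(co_v$tables[[1]]$values, 2, sd)
  expect_true(all(abs(sds / (0.15 / 2) - 1) < 0.05))
})

test_that("null cohorts show no spurious connection effects", {
  # package generator, 20 seeds, vs a brute-force Monte-Carlo null of max|d|
  n <- 200; n_rois <- 10
  map <- edge_index_map(n_rois)
  max_d <- function(X, labels) max(effect_table(X, labels, sort = FALSE)$d)
  got <- vapply(1:20, function(s) {
    co <- quick_cohort(n, n, n_rois, seed = 300 + s)
    max_d(build_feature_table(co$tables[[1]]), co$labels)
  }, numeric(1))
  null_max <- withr::with_seed(77, vapply(1:100, function(i) {
    vals <- matrix(rnorm(2 * n * n_rois, sd = 0.15), 2 * n)
    X <- abs(vals[, map$i] - vals[, map$j])
    max_d(X, rep(c("A", "B"), each = n))
  }, numeric(1)))
  expect_lt(mean(got), quantile(null_max, 0.99))
})

test_that("cohort CSV and flat config round-trip", {
  co <- quick_cohort(n_a = 5, n_b = 4, n_rois = 4,
                     measurements = c("cortical_thickness", "sulcal_depth"),
                     seed = 2)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  back <- read_cohort_csv(f)
  expect_equal(back$tables[["cortical_thickness|lh"]]$values,
               co$tables[["cortical_thickness|lh"]]$values)
  expect_equal(as.character(back$labels), as.character(co$labels))
  unlink(f)

  cfgf <- tempfile(fileext = ".cfg")
  writeLines(c("# demo synthetic config",
               "n_group_a = 6", "n_group_b = 7", "n_rois = 5",
               "measurements = cortical_thickness, sulcal_depth",
               "baseline_sd_cortical_thickness = 0.2",
               "effect = cortical_thickness, 2, B, 0.4",
               "effect = sulcal_depth, 3, A, -0.1",
               "seed = 9"), cfgf)
  cfg <- read_synthetic_config(cfgf)
  expect_s3_class(cfg, "cmn_synth_config")
  expect_equal(cfg$n_group_b, 7L)
  expect_equal(cfg$baseline_sd$cortical_thickness, rep(0.2, 5))
  expect_equal(nrow(cfg$injected_effects), 2)
  expect_equal(cfg$injected_effects$mean_shift, c(0.4, -0.1))
  unlink(cfgf)
})
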