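# Hand-built scheme rankings for the algebraic cases.
mk_ranking <- function(weights, k_f, meas = "m1", hemi = "lh",
                       kind = "loo") {
  structure(list(scheme = cv_scheme(kind), measurement = meas,
                 hemisphere = hemi, weights = weights,
                 top_set = order(-weights,
                                 seq_along(weights))[seq_len(k_f)],
                 k_f = as.integer(k_f), n_features = length(weights),
                 columns = seq_along(weights)),
            class = "cmn_scheme_ranking")
}

test_that("identical schemes aggregate idempotently (raw scale)", {
  w <- c(5, 4, 3, 2, 1, 0.5) / 10
  rks <- list(mk_ranking(w, 3, kind = "loo"),
              mk_ranking(w, 3, kind = "5fold"),
              mk_ranking(w, 3, kind = "10fold"))
  agg <- aggregate_schemes(rks, normalize = FALSE)
  expect_equal(nrow(agg$edges), 3)             # union size k_f
  expect_equal(agg$edges$edge, 1:3)
  expect_equal(agg$edges$weight, w[1:3])       # mean of identical values
})

test_that("an edge in one scheme's top set contributes w/3", {
  w1 <- c(0.9, 0.5, 0.1, 0.05)
  w2 <- c(0.0, 0.5, 0.4, 0.05)                 # edge 1 not in top-2 here
  rks <- list(mk_ranking(w1, 2, kind = "loo"),
              mk_ranking(w2, 2, kind = "5fold"),
              mk_ranking(w2, 2, kind = "10fold"))
  agg <- aggregate_schemes(rks, normalize = FALSE)
  e1 <- agg$edges$weight[agg$edges$edge == 1]
  expect_equal(e1, 0.9 / 3)
  e2 <- agg$edges$weight[agg$edges$edge == 2]
  expect_equal(e2, 0.5)                        # present in all three
})

test_that("disjoint top sets give a union of size 3 * k_f", {
  w1 <- c(9, 8, 0, 0, 0, 0) ; w2 <- c(0, 0, 9, 8, 0, 0)
  w3 <- c(0, 0, 0, 0, 9, 8)
  rks <- list(mk_ranking(w1, 2, kind = "loo"),
              mk_ranking(w2, 2, kind = "5fold"),
              mk_ranking(w3, 2, kind = "10fold"))
  agg <- aggregate_schemes(rks)
  expect_equal(nrow(agg$edges), 6)
  expect_gte(nrow(agg$edges), rks[[1]]$k_f)    # k_f' >= k_f
})

test_that("mismatched contexts and parameters are rejected", {
  w <- runif(5)
  expect_error(aggregate_schemes(list(mk_ranking(w, 2, meas = "m1"),
                                      mk_ranking(w, 2, meas = "m2"))),
               "context")
  expect_error(aggregate_schemes(list(mk_ranking(w, 2),
                                      mk_ranking(w, 3))),
               "k_f")
})

test_that("cross-measurement aggregation reduces and ranks correctly", {
  w <- c(0.8, 0.6, 0.4, 0.2, 0.1, 0)
  one <- aggregate_schemes(list(mk_ranking(w, 3, "mA"),
                                mk_ranking(w, 3, "mA", kind = "5fold")),
                           normalize = FALSE)
  fin <- aggregate_measurements(list(one), k_f = 3)
  expect_equal(fin$edges$edge, 1:3)            # reduces to its own top-k_f
  expect_equal(fin$edges$weight, w[1:3])

  # an edge top in all measurements beats an edge top in only one
  wX <- c(0.5, 0, 0, 0, 0, 0)                  # edge 1 everywhere
  wY <- c(0, 0.5, 0, 0, 0, 0)                  # edge 2 in one measurement
  per_meas <- list(
    aggregate_schemes(list(mk_ranking(wX + wY, 2, "m1")),
                      normalize = FALSE),
    aggregate_schemes(list(mk_ranking(wX, 1, "m2")), normalize = FALSE),
    aggregate_schemes(list(mk_ranking(wX, 1, "m3")), normalize = FALSE))
  fin2 <- aggregate_measurements(per_meas, k_f = 2)
  expect_equal(fin2$edges$edge[1], 1)
  w1 <- fin2$edges$weight[fin2$edges$edge == 1]
  w2 <- fin2$edges$weight[fin2$edges$edge == 2]
  expect_gt(w1, w2)
  expect_equal(w2, 0.5 / 3)                    # absent measurements add 0
})

test_that("every final edge appears in some scheme top set (containment)", {
  co <- quick_cohort(n_a = 12, n_b = 12, n_rois = 8,
                     measurements = c("cortical_thickness", "sulcal_depth"),
                     seed = 60)
  per_meas <- lapply(c("cortical_thickness", "sulcal_depth"), function(m) {
    X <- build_feature_table(co$tables[[paste0(m, "|lh")]])
    rks <- lapply(default_schemes(seed = 3), function(s)
      scheme_ranking(X, co$labels, s, infs_params(), k_f = 4,
                     measurement = m, hemisphere = "lh"))
    list(agg = aggregate_schemes(rks), tops = lapply(rks, `[[`, "top_set"))
  })
  fin <- aggregate_measurements(lapply(per_meas, `[[`, "agg"), k_f = 4)
  all_tops <- unlist(lapply(per_meas, `[[`, "tops"))
  expect_true(all(fin$edges$edge %in% all_tops))
  expect_equal(fin$edges$roi_a,
               sub("\\|.*$", "", fin$edges$edge_name))
})

test_that("reproducibility_report recovers a strong injected connection", {
  meas <- c("cortical_thickness", "sulcal_depth")
  deltas <- vapply(meas, function(m)
    delta_for_target_d(m, 2.0, roi_i = 2, roi_j = 5, n_rois = 8),
    numeric(1))
  eff <- opposed_effect(meas, 2, 5, deltas)
  co <- quick_cohort(n_a = 30, n_b = 30, n_rois = 8, measurements = meas,
                     effects = eff, seed = 61)
  tabs <- list(cortical_thickness =
                 build_feature_table(co$tables[["cortical_thickness|lh"]]),
               sulcal_depth =
                 build_feature_table(co$tables[["sulcal_depth|lh"]]))
  # dispersion-dominant alpha gives a clean machinery check; the default
  # alpha = 0.5 trade-off is exercised at scale in test-acceptance.R
  rep <- reproducibility_report(tabs, co$labels,
                                schemes = default_schemes(seed = 5),
                                params = infs_params(alpha = 0.8),
                                k_f = 3, hemisphere = "lh")
  map <- edge_index_map(8)
  target <- which(map$i == 2 & map$j == 5)
  expect_equal(rep$final$edges$edge[1], target)
  expect_true("cohens_d" %in% names(rep$final$edges))
  expect_gt(rep$final$edges$cohens_d[1], 1)
  # writers
  f <- tempfile(fileext = ".csv"); g <- tempfile(fileext = ".txt")
  write_report_csv(rep, f, g)
  expect_equal(read.csv(f)$rank, seq_len(3))
  expect_length(readLines(g), 3)
  unlink(c(f, g))
})
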