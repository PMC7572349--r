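test_that("fold assignment is deterministic, stratified and LOO-compatible", {
  labels <- factor(rep(c("A", "B"), times = c(12, 18)))
  loo <- make_folds(labels, cv_scheme("loo"))
  expect_length(loo, 30)
  expect_equal(sort(unlist(loo)), 1:30)

  sch <- cv_scheme("kfold", n_folds = 5, seed = 3)
  f1 <- make_folds(labels, sch)
  f2 <- make_folds(labels, sch)
  expect_identical(f1, f2)
  sizes <- lengths(f1)
  expect_true(all(sizes == 6))
  for (f in f1) {                      # stratification within +/- 1
    tab <- table(labels[f])
    expect_true(all(abs(tab - c(12, 18) / 5) <= 1))
  }
  f3 <- make_folds(labels, cv_scheme("kfold", n_folds = 5, seed = 4))
  expect_false(identical(f1, f3))

  # n_folds = n reproduces the LOO partition
  fn <- make_folds(labels, cv_scheme("kfold", n_folds = 30, seed = 1))
  expect_equal(sort(unlist(lapply(fn, sort))), 1:30)
  expect_true(all(lengths(fn) == 1))
})

test_that("run_cv validates its preconditions", {
  co <- quick_cohort(n_a = 8, n_b = 8, n_rois = 6, seed = 50)
  X <- build_feature_table(co$tables[[1]])
  expect_error(run_cv(X, co$labels, cv_scheme("loo"), K = 100),
               "K must be")
  expect_error(run_cv(X, co$labels, cv_scheme("kfold", n_folds = 30),
                      K = 5),
               "n_folds")
  expect_error(run_cv(X, rep("A", 16), cv_scheme("loo"), K = 5),
               "two classes")
})

test_that("LOO yields n held-out predictions and equals n-fold CV", {
  delta <- delta_for_target_d("cortical_thickness", 2.5, roi_i = 1,
                              roi_j = 4, n_rois = 6)
  co <- quick_cohort(n_a = 10, n_b = 10, n_rois = 6,
                     effects = opposed_effect("cortical_thickness", 1, 4,
                                              delta),
                     seed = 51)
  X <- build_feature_table(co$tables[[1]])
  r_loo <- run_cv(X, co$labels, cv_scheme("loo", seed = 5), K = 10)
  expect_length(r_loo$predictions, 20)
  expect_length(r_loo$folds, 20)
  r_n <- run_cv(X, co$labels, cv_scheme("kfold", n_folds = 20, seed = 5),
                K = 10)
  expect_equal(r_n$accuracy, r_loo$accuracy)
  # determinism of the whole result
  r_loo2 <- run_cv(X, co$labels, cv_scheme("loo", seed = 5), K = 10)
  expect_identical(r_loo$predictions, r_loo2$predictions)
  expect_identical(r_loo$per_fold, r_loo2$per_fold)
})

test_that("feature ranking is computed on training subjects only", {
  co <- quick_cohort(n_a = 12, n_b = 12, n_rois = 6, seed = 52)
  X <- build_feature_table(co$tables[[1]])
  params <- infs_params()
  res <- run_cv(X, co$labels, cv_scheme("kfold", n_folds = 4, seed = 9),
                K = 5, params = params)
  for (f in c(1, 3)) {       # recompute two folds independently
    train <- setdiff(seq_len(24), res$folds[[f]])
    sc <- infs_scores(feature_adjacency(X[train, ], params), params$r)
    expect_equal(res$per_fold[[f]]$top_features,
                 rank_features(sc)$ranks[1:5])
  }
})

test_that("a label-copy canary outside the usable columns stays at chance", {
  co <- quick_cohort(n_a = 25, n_b = 25, n_rois = 8, seed = 53)
  X <- build_feature_table(co$tables[[1]])
  canary <- as.numeric(co$labels == "B")
  Xc <- cbind(X, canary = canary)
  sch <- cv_scheme("kfold", n_folds = 5, seed = 11)
  # canary visible: the high-dispersion label copy is selected and the
  # classifier becomes (near) perfect ...
  acc_leaky <- run_cv(Xc, co$labels, sch, K = 10)$accuracy
  expect_gte(acc_leaky, 0.95)
  # ... excluded from the usable columns, nothing leaks and accuracy is
  # at chance on pure noise
  acc_pure <- run_cv(Xc, co$labels, sch, K = 10,
                     columns = seq_len(ncol(X)))$accuracy
  expect_gte(acc_pure, 0.25)
  expect_lte(acc_pure, 0.72)
})

test_that("accuracy_report averages schemes and flags missing cells", {
  mk <- function(meas, hemi, kind, acc) {
    structure(list(scheme = cv_scheme(kind), measurement = meas,
                   hemisphere = hemi, accuracy = acc),
              class = "cmn_cv_result")
  }
  res <- list(mk("m1", "lh", "loo", 0.6), mk("m1", "lh", "5fold", 0.7),
              mk("m1", "lh", "10fold", 0.8))
  rep <- accuracy_report(res)
  expect_equal(rep$mean_accuracy, 0.7)
  expect_equal(rep$loo, 0.6)
  res2 <- c(res, list(mk("m2", "lh", "loo", 0.5)))
  expect_error(accuracy_report(res2), "m2/lh")
})

test_that("scheme_ranking averages fold scores and respects k_f", {
  co <- quick_cohort(n_a = 10, n_b = 10, n_rois = 6, seed = 54)
  X <- build_feature_table(co$tables[[1]])
  sch <- cv_scheme("kfold", n_folds = 5, seed = 2)
  params <- infs_params()
  rk <- scheme_ranking(X, co$labels, sch, params, k_f = 3,
                       measurement = "m", hemisphere = "lh")
  folds <- make_folds(co$labels, sch)
  manual <- rowMeans(vapply(folds, function(te)
    infs_scores(feature_adjacency(X[-te, ], params), params$r),
    numeric(ncol(X))))
  expect_equal(unname(rk$weights), unname(manual), tolerance = 1e-12)
  expect_length(rk$top_set, 3)
  expect_equal(rk$top_set, rank_features(manual)$ranks[1:3])
  expect_error(scheme_ranking(X, co$labels, sch, params, k_f = 100), "k_f")
})
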