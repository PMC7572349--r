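#' End-to-end pipeline configuration
#'
#' Either `synthetic` (a [synthetic_config()]) or `input` (a tidy cohort CSV
#' path) must be supplied.  All numeric choices are recorded in the run's
#' provenance log.
#'
#' @param synthetic Optional [synthetic_config()] driving cohort simulation.
#' @param input Optional path to a tidy cohort CSV (see
#'   [read_cohort_csv()]).
#' @param hemispheres Hemispheres to run (default both; intersected with
#'   what the data provides).
#' @param measurements Measurements to run (default: all present).
#' @param alpha,r,standardize inFS parameters (see [infs_params()]).
#' @param K Top features fed to the classifier.
#' @param k_f Top-set size for the reproducibility aggregation.
#' @param schemes Character subset of `c("loo", "5fold", "10fold")` or
#'   `"all"`.
#' @param classify Run the SVM classification stage (default TRUE).
#' @param costs Cost grid for nested tuning.
#' @param seed Master seed; every stage seed derives from it.
#' @param outdir Output directory (created if needed).
#' @return Object of class `cmn_pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, input = NULL,
                            hemispheres = c("lh", "rh"),
                            measurements = NULL,
                            alpha = 0.5, r = 0.01, standardize = FALSE,
                            K = 100L, k_f = 5L,
                            schemes = c("loo", "5fold", "10fold"),
                            classify = TRUE, costs = 10^(-3:3),
                            seed = 42L, outdir = tempfile("cmnet_run_")) {
  if (identical(schemes, "all")) schemes <- c("loo", "5fold", "10fold")
  structure(list(synthetic = synthetic, input = input,
                 hemispheres = hemispheres, measurements = measurements,
                 alpha = alpha, r = r, standardize = isTRUE(standardize),
                 K = K, k_f = k_f, schemes = schemes,
                 classify = isTRUE(classify), costs = costs,
                 seed = as.integer(seed), outdir = outdir),
            class = "cmn_pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @return Character vector of problems, each naming the offending field;
#'   empty when the config is valid.
#' @export
validate_config <- function(config) {
  problems <- character()
  add <- function(p) problems <<- c(problems, p)
  if (is.null(config$synthetic) && is.null(config$input))
    add("input/synthetic: either an input cohort CSV or a synthetic config is required")
  if (!is.null(config$synthetic) &&
      !inherits(config$synthetic, "cmn_synth_config"))
    add("synthetic: must be created by synthetic_config()")
  if (!is.null(config$input) && !file.exists(config$input))
    add(sprintf("input: file does not exist: %s", config$input))
  if (!is.numeric(config$alpha) || length(config$alpha) != 1 ||
      is.na(config$alpha) || config$alpha < 0 || config$alpha > 1)
    add("alpha: must be a scalar in [0, 1]")
  if (!is.numeric(config$r) || length(config$r) != 1 || is.na(config$r) ||
      config$r <= 0)
    add("r: must be a positive scalar")
  if (!is_count(config$K, 1)) add("K: must be a positive integer")
  if (!is_count(config$k_f, 1)) add("k_f: must be a positive integer")
  bad <- setdiff(config$schemes, c("loo", "5fold", "10fold"))
  if (length(bad) || !length(config$schemes))
    add(sprintf("schemes: must be a non-empty subset of loo/5fold/10fold%s",
                if (length(bad)) paste0(" (got ",
                                        paste(bad, collapse = ","), ")")
                else ""))
  if (!is_count(abs(config$seed), 0)) add("seed: must be an integer")
  if (!is.null(config$synthetic) &&
      inherits(config$synthetic, "cmn_synth_config")) {
    n_f <- config$synthetic$n_rois * (config$synthetic$n_rois - 1) / 2
    if (is_count(config$k_f, 1) && config$k_f > n_f)
      add(sprintf("k_f: exceeds the feature count n_f = %d", n_f))
    if (is_count(config$K, 1) && config$K > n_f)
      add(sprintf("K: exceeds the feature count n_f = %d", n_f))
  }
  problems
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  message(sprintf("[cmnet] stage %-12s ...", name), appendLF = FALSE)
  out <- tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  message(sprintf(" done (%.2fs)", proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full discriminative-connection pipeline
#'
#' Simulate (or load) the cohort, build per-subject CMN feature tables, run
#' per-scheme cross-validated classification, aggregate top connections
#' across schemes and measurements, compute Cohen's d for the final edges,
#' and write all stage outputs plus a machine-readable `summary.json` (with
#' full parameter provenance) to the configured output directory.  The
#' summary is byte-identical across runs with the same config and seed.
#'
#' @param config A valid [pipeline_config()].
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stopf("invalid pipeline config:\n- %s",
          paste(problems, collapse = "\n- "))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  params <- infs_params(config$alpha, config$r, config$standardize)

  cohort <- .stage("cohort", {
    if (!is.null(config$synthetic)) {
      co <- simulate_cohort(config$synthetic)
      write_cohort_csv(co, file.path(config$outdir, "cohort.csv"))
      write_truth_csv(co, file.path(config$outdir, "truth.csv"))
      co
    } else read_cohort_csv(config$input)
  })

  hemis <- intersect(config$hemispheres,
                     unique(vapply(cohort$tables, `[[`, "", "hemisphere")))
  meas <- config$measurements %||%
    unique(vapply(cohort$tables, `[[`, "", "measurement"))
  if (!length(hemis)) stopf("no requested hemisphere present in the data")
  if (!length(meas)) stopf("no measurements to run")

  feats <- .stage("build-cmn", {
    out <- list()
    for (h in hemis) {
      out[[h]] <- list()
      for (m in meas) {
        key <- paste(m, h, sep = "|")
        if (is.null(cohort$tables[[key]]))
          stopf("no attribute table for %s", key)
        out[[h]][[m]] <- build_feature_table(cohort$tables[[key]])
      }
    }
    out
  })
  n_f <- ncol(feats[[1]][[1]])
  if (config$K > n_f)
    stopf("K = %d exceeds n_f = %d for this parcellation", config$K, n_f)
  if (config$k_f > n_f) stopf("k_f = %d exceeds n_f = %d", config$k_f, n_f)

  scheme_of <- function(label, seed) {
    switch(label,
           loo = cv_scheme("loo", seed = seed),
           `5fold` = cv_scheme("kfold", n_folds = 5L, seed = seed),
           `10fold` = cv_scheme("kfold", n_folds = 10L, seed = seed))
  }

  cv_results <- list()
  reports <- list()
  idx <- 0L
  for (h in hemis) {
    per_meas <- list()
    for (m in meas) {
      X <- feats[[h]][[m]]
      rks <- list()
      for (s in config$schemes) {
        idx <- idx + 1L
        sch <- scheme_of(s, config$seed + 101L * idx)
        folds <- make_folds(cohort$labels, sch)
        fs <- .stage(sprintf("select %s/%s/%s", m, h, s),
                     .fold_infs_scores(X, folds, params))
        rks[[s]] <- scheme_ranking(X, cohort$labels, sch, params,
                                   k_f = config$k_f, fold_scores = fs,
                                   measurement = m, hemisphere = h)
        if (config$classify) {
          cv_results[[length(cv_results) + 1L]] <-
            .stage(sprintf("classify %s/%s/%s", m, h, s),
                   run_cv(X, cohort$labels, sch, K = config$K,
                          params = params, costs = config$costs,
                          fold_scores = fs, measurement = m,
                          hemisphere = h))
        }
        write_ranking_csv(rank_features(rks[[s]]$weights, params),
                          file.path(config$outdir,
                                    sprintf("scores_%s_%s_%s.csv",
                                            m, h, s)))
      }
      per_meas[[m]] <- aggregate_schemes(rks)
    }
    reports[[h]] <- .stage(sprintf("aggregate %s", h), {
      final <- aggregate_measurements(per_meas, k_f = config$k_f)
      eff <- do.call(rbind, lapply(meas, function(m) {
        tab <- effect_table(feats[[h]][[m]], cohort$labels,
                            edges = final$edges$edge, sort = FALSE)
        tab$measurement <- m
        tab
      }))
      d_mat <- matrix(eff$d, nrow = nrow(final$edges))
      final$edges$cohens_d <- rowMeans(d_mat)
      rep <- structure(list(per_measurement = per_meas, final = final,
                            effects = eff, hemisphere = h,
                            k_f = config$k_f),
                       class = "cmn_reproducibility_report")
      write_report_csv(rep, file.path(config$outdir,
                                      sprintf("report_%s.csv", h)),
                       file.path(config$outdir,
                                 sprintf("top_edges_%s.txt", h)))
      utils::write.csv(eff, file.path(config$outdir,
                                      sprintf("effects_%s.csv", h)),
                       row.names = FALSE, quote = FALSE)
      rep
    })
  }

  acc <- NULL
  if (config$classify) {
    acc <- accuracy_report(cv_results)
    utils::write.csv(acc, file.path(config$outdir, "accuracy.csv"),
                     row.names = FALSE, quote = FALSE)
    costs_log <- lapply(cv_results, function(r)
      list(measurement = r$measurement, hemisphere = r$hemisphere,
           scheme = format(r$scheme),
           tuned_costs = vapply(r$per_fold, `[[`, numeric(1),
                                "tuned_cost")))
    jsonlite::write_json(costs_log,
                         file.path(config$outdir, "tuned_costs.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  summary <- list(
    parameters = list(alpha = config$alpha, r = config$r,
                      standardize = config$standardize, K = config$K,
                      k_f = config$k_f, schemes = config$schemes,
                      costs = config$costs, seed = config$seed,
                      n_f = n_f, measurements = meas,
                      hemispheres = hemis,
                      n_subjects = length(cohort$subjects)),
    accuracy = acc,
    final_top = lapply(reports, function(r)
      r$final$edges[setdiff(names(r$final$edges), "edge")]),
    effects = lapply(reports, `[[`, "effects"))
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("[cmnet] run complete: %s", config$outdir))
  invisible(summary)
}
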