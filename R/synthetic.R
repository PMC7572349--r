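#' Configuration for a synthetic two-group cohort
#'
#' Describes the generative world emulating a two-group (e.g. male/female)
#' cohort of ROI-level cortical attribute values: independent Gaussian noise
#' per ROI around a per-measurement baseline mean, with optional group mean
#' shifts ("injected effects") on chosen ROIs.  Connectivity is a
#' deterministic function of ROI values, so ROI-level shifts translate into
#' connection-level effect sizes via [expected_connection_effect()].
#'
#' Baselines default to equal means across ROIs at a realistic per-measurement
#' scale (thickness ~2.5 mm, sulcal depth ~1.5, curvatures ~0.1), so under the
#' null every connection has the same folded-normal distribution and no edge
#' is structurally favoured.
#'
#' @param n_group_a,n_group_b Subjects per group (defaults 308 and 390,
#'   mirroring a typical large two-group study).
#' @param n_rois Number of regions per hemisphere (default 35).
#' @param measurements Character vector of measurement identifiers.
#' @param baseline_means Per-measurement baseline mean: scalar, length-`n_rois`
#'   vector, or named list per measurement of either.
#' @param baseline_sd Per-ROI noise standard deviation: scalar, vector, or
#'   named list per measurement.  Must be strictly positive.
#' @param injected_effects `NULL` or a data.frame with columns `measurement`,
#'   `roi_index` (1-based), `group` (one of `group_labels`), `mean_shift`.
#' @param vertices_per_roi Optional vertex count per ROI; when set, vertex
#'   values are generated and ROI-averaged (effective ROI noise
#'   `sd/sqrt(V)`).
#' @param hemispheres Hemisphere labels to generate (independently).
#' @param group_labels Length-2 character vector of group names.
#' @param seed Integer RNG seed; identical configs reproduce identical
#'   cohorts bit for bit.
#' @return An object of class `cmn_synth_config`.
#' @seealso [simulate_cohort()], [expected_connection_effect()]
#' @export
synthetic_config <- function(n_group_a = 308L, n_group_b = 390L,
                             n_rois = 35L,
                             measurements = cmn_measurements(),
                             baseline_means = NULL,
                             baseline_sd = NULL,
                             injected_effects = NULL,
                             vertices_per_roi = NULL,
                             hemispheres = c("lh", "rh"),
                             group_labels = c("A", "B"),
                             seed = 42L) {
  if (!is_count(n_group_a, 2)) stopf("n_group_a must be an integer >= 2")
  if (!is_count(n_group_b, 2)) stopf("n_group_b must be an integer >= 2")
  if (!is_count(n_rois, 2)) stopf("n_rois must be an integer >= 2")
  if (!is.character(measurements) || !length(measurements) ||
      anyDuplicated(measurements))
    stopf("measurements must be distinct non-empty identifiers")
  if (length(group_labels) != 2L || anyDuplicated(group_labels))
    stopf("group_labels must be two distinct labels")
  if (!is.null(vertices_per_roi) && !is_count(vertices_per_roi, 1))
    stopf("vertices_per_roi must be a positive integer or NULL")
  if (!is_count(abs(seed), 0)) stopf("seed must be an integer")

  means <- .expand_per_measurement(baseline_means, measurements, n_rois,
                                   default = .default_baseline,
                                   what = "baseline_means")
  sds <- .expand_per_measurement(baseline_sd, measurements, n_rois,
                                 default = .default_sd,
                                 what = "baseline_sd")
  for (m in measurements)
    if (any(!is.finite(sds[[m]])) || any(sds[[m]] <= 0))
      stopf("baseline_sd must be > 0 for every ROI (measurement '%s')", m)

  eff <- .check_effects(injected_effects, measurements, n_rois, group_labels)

  structure(list(n_group_a = as.integer(n_group_a),
                 n_group_b = as.integer(n_group_b),
                 n_rois = as.integer(n_rois),
                 measurements = measurements,
                 baseline_means = means,
                 baseline_sd = sds,
                 injected_effects = eff,
                 vertices_per_roi = if (is.null(vertices_per_roi)) NULL
                                    else as.integer(vertices_per_roi),
                 hemispheres = hemispheres,
                 group_labels = group_labels,
                 seed = as.integer(seed)),
            class = "cmn_synth_config")
}

# Realistic per-measurement scales; constant across ROIs (see vignette).
.default_baseline <- c(max_principal_curvature = 0.12,
                       cortical_thickness = 2.5,
                       sulcal_depth = 1.5,
                       average_curvature = 0.08)
.default_sd <- c(max_principal_curvature = 0.02,
                 cortical_thickness = 0.15,
                 sulcal_depth = 0.6,
                 average_curvature = 0.015)

.expand_per_measurement <- function(x, measurements, n_rois, default, what) {
  one <- function(v, m) {
    if (is.null(v)) {
      v <- if (m %in% names(default)) default[[m]] else unname(default[1])
    }
    if (!is.numeric(v) || !(length(v) %in% c(1L, n_rois)))
      stopf("%s for measurement '%s' must be a scalar or length-%d vector",
            what, m, n_rois)
    if (any(!is.finite(v))) stopf("%s contains non-finite values", what)
    rep_len(as.numeric(v), n_rois)
  }
  if (is.list(x)) {
    out <- lapply(measurements, function(m) one(x[[m]], m))
  } else {
    out <- lapply(measurements, function(m) one(x, m))
  }
  names(out) <- measurements
  out
}

.check_effects <- function(eff, measurements, n_rois, group_labels) {
  if (is.null(eff))
    return(data.frame(measurement = character(), roi_index = integer(),
                      group = character(), mean_shift = numeric()))
  need <- c("measurement", "roi_index", "group", "mean_shift")
  if (!is.data.frame(eff) || !all(need %in% names(eff)))
    stopf("injected_effects must be a data.frame with columns %s",
          paste(need, collapse = ", "))
  if (!all(eff$measurement %in% measurements))
    stopf("injected_effects: unknown measurement(s): %s",
          paste(setdiff(eff$measurement, measurements), collapse = ", "))
  if (any(eff$roi_index < 1 | eff$roi_index > n_rois |
          eff$roi_index != floor(eff$roi_index)))
    stopf("injected_effects: roi_index must be an integer in 1..%d", n_rois)
  if (!all(eff$group %in% group_labels))
    stopf("injected_effects: group must be one of %s",
          paste(group_labels, collapse = ", "))
  if (any(!is.finite(eff$mean_shift)))
    stopf("injected_effects: mean_shift must be finite")
  eff[need]
}

# Sum of injected mean shifts for (measurement, roi, group).
.shift_for <- function(config, measurement, roi, group) {
  e <- config$injected_effects
  sel <- e$measurement == measurement & e$roi_index == roi & e$group == group
  if (!any(sel)) 0 else sum(e$mean_shift[sel])
}

#' Simulate a synthetic two-group cohort
#'
#' Draws each subject's ROI value for measurement `m`, ROI `i` independently
#' from `N(mean + shift, sd^2)`, where the shift applies only to subjects of
#' the group named by a matching injected effect.  Hemispheres are generated
#' by the same procedure, independently.  With `vertices_per_roi = V`, vertex
#' values are drawn at the stated sd and ROI-averaged, which is
#' distributionally identical to ROI-level generation at `sd/sqrt(V)`.
#'
#' @param config A [synthetic_config()] object.
#' @return An object of class `cmn_cohort`: list with `subjects`, `labels`
#'   (factor with two levels), `tables` (one attribute table per
#'   measurement/hemisphere, each a list with `measurement`, `hemisphere`,
#'   `values` subjects x n_rois matrix, `labels`), `truth` (the injected
#'   effects) and `config`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cmn_synth_config"))
    stopf("config must be created by synthetic_config()")
  n <- config$n_group_a + config$n_group_b
  subjects <- sprintf("sub-%04d", seq_len(n))
  labels <- factor(rep(config$group_labels, c(config$n_group_a,
                                              config$n_group_b)),
                   levels = config$group_labels)
  roi_names <- .roi_names(config$n_rois)
  V <- config$vertices_per_roi

  tables <- list()
  withr::with_seed(config$seed, {
    for (h in config$hemispheres) {
      for (m in config$measurements) {
        mu <- matrix(rep(config$baseline_means[[m]], each = n), n,
                     config$n_rois)
        for (g in config$group_labels) {
          rows <- labels == g
          for (roi in seq_len(config$n_rois)) {
            s <- .shift_for(config, m, roi, g)
            if (s != 0) mu[rows, roi] <- mu[rows, roi] + s
          }
        }
        sdv <- config$baseline_sd[[m]]
        if (is.null(V)) {
          vals <- mu + matrix(rnorm(n * config$n_rois), n) *
            rep(sdv, each = n)
        } else {
          # vertex-level draws, ROI-averaged
          vals <- mu
          for (roi in seq_len(config$n_rois)) {
            vv <- matrix(rnorm(n * V, sd = sdv[roi]), n, V)
            vals[, roi] <- mu[, roi] + rowMeans(vv)
          }
        }
        dimnames(vals) <- list(subjects, roi_names)
        tables[[paste(m, h, sep = "|")]] <-
          structure(list(measurement = m, hemisphere = h, values = vals,
                         labels = labels),
                    class = "cmn_attribute_table")
      }
    }
  })

  structure(list(subjects = subjects, labels = labels, tables = tables,
                 truth = config$injected_effects, config = config),
            class = "cmn_cohort")
}

.roi_names <- function(n_rois) {
  if (n_rois == 35L) dk_regions() else sprintf("roi%02d", seq_len(n_rois))
}

#' @export
print.cmn_cohort <- function(x, ...) {
  cat(sprintf("cmn_cohort: %d subjects (%s), %d table(s), %d ROIs\n",
              length(x$subjects),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", "),
              length(x$tables), x$config$n_rois))
  invisible(x)
}

# Folded-normal moments: X ~ N(mu, s^2), returns mean and sd of |X|.
.folded_moments <- function(mu, s) {
  fm <- s * sqrt(2 / pi) * exp(-mu^2 / (2 * s^2)) +
    mu * (1 - 2 * pnorm(-mu / s))
  fv <- mu^2 + s^2 - fm^2
  c(mean = fm, sd = sqrt(pmax(fv, 0)))
}

#' Theoretical Cohen's d of a connection under a synthetic config
#'
#' Closed-form population effect size of the connection between two ROIs
#' implied by the generative model: the connection value is
#' `|m_i - m_j|`, a folded normal in each group, with location equal to the
#' baseline gap plus the group's net injected shift and scale
#' `sqrt(sd_i^2 + sd_j^2) / sqrt(V)`.  Cohen's d uses the absolute mean
#' difference divided by the average of the two group standard deviations.
#'
#' @param config A [synthetic_config()].
#' @param measurement Measurement identifier.
#' @param roi_i,roi_j Distinct 1-based ROI indices.
#' @return Theoretical Cohen's d (nonnegative scalar).
#' @export
expected_connection_effect <- function(config, measurement, roi_i, roi_j) {
  if (!inherits(config, "cmn_synth_config"))
    stopf("config must be created by synthetic_config()")
  if (!measurement %in% config$measurements)
    stopf("unknown measurement '%s'", measurement)
  if (!is_count(roi_i) || !is_count(roi_j) ||
      roi_i > config$n_rois || roi_j > config$n_rois)
    stopf("roi_i and roi_j must be ROI indices in 1..%d", config$n_rois)
  if (roi_i == roi_j) stopf("roi_i and roi_j must be distinct")

  means <- config$baseline_means[[measurement]]
  sds <- config$baseline_sd[[measurement]]
  V <- if (is.null(config$vertices_per_roi)) 1L else config$vertices_per_roi
  s <- sqrt(sds[roi_i]^2 + sds[roi_j]^2) / sqrt(V)
  gap <- means[roi_i] - means[roi_j]

  mom <- lapply(config$group_labels, function(g) {
    mu <- gap + .shift_for(config, measurement, roi_i, g) -
      .shift_for(config, measurement, roi_j, g)
    .folded_moments(mu, s)
  })
  a <- mom[[1]]; b <- mom[[2]]
  stdm <- (a[["sd"]] + b[["sd"]]) / 2
  if (stdm == 0) return(0)
  abs(b[["mean"]] - a[["mean"]]) / stdm
}

#' Write / read a cohort as tidy CSV
#'
#' Long format with columns `subject_id`, `group`, `hemisphere`,
#' `measurement`, `roi_name`, `value`.
#'
#' @param cohort A `cmn_cohort`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  rows <- lapply(cohort$tables, function(tb) {
    n <- nrow(tb$values); p <- ncol(tb$values)
    data.frame(subject_id = rep(rownames(tb$values), p),
               group = rep(as.character(tb$labels), p),
               hemisphere = tb$hemisphere,
               measurement = tb$measurement,
               roi_name = rep(colnames(tb$values), each = n),
               value = as.vector(tb$values))
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "hemisphere", "measurement", "roi_name",
            "value")
  if (!all(need %in% names(df)))
    stopf("cohort CSV must have columns %s", paste(need, collapse = ", "))
  subjects <- unique(df$subject_id)
  grp <- df$group[match(subjects, df$subject_id)]
  glev <- unique(grp)
  if (length(glev) != 2L) stopf("cohort must contain exactly two groups")
  labels <- factor(grp, levels = glev)
  tables <- list()
  for (key in unique(paste(df$measurement, df$hemisphere, sep = "|"))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    sub <- df[df$measurement == parts[1] & df$hemisphere == parts[2], ]
    rois <- unique(sub$roi_name)
    vals <- matrix(NA_real_, length(subjects), length(rois),
                   dimnames = list(subjects, rois))
    vals[cbind(match(sub$subject_id, subjects),
               match(sub$roi_name, rois))] <- sub$value
    if (anyNA(vals)) stopf("missing values for %s", key)
    tables[[key]] <- structure(list(measurement = parts[1],
                                    hemisphere = parts[2],
                                    values = vals, labels = labels),
                               class = "cmn_attribute_table")
  }
  structure(list(subjects = subjects, labels = labels, tables = tables,
                 truth = NULL, config = NULL), class = "cmn_cohort")
}

#' Write the injected ground truth as CSV
#'
#' @param cohort A `cmn_cohort` (or a `cmn_synth_config`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(cohort, path) {
  truth <- if (inherits(cohort, "cmn_synth_config")) cohort$injected_effects
           else cohort$truth
  if (is.null(truth))
    truth <- data.frame(measurement = character(), roi_index = integer(),
                        group = character(), mean_shift = numeric())
  write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a synthetic-cohort configuration from a flat key/value file
#'
#' Format: one `key = value` per line, `#` comments, comma-separated lists,
#' and one `effect = measurement,roi_index,group,mean_shift` line per
#' injected effect.  Per-measurement baselines use keys
#' `baseline_mean_<measurement>` and `baseline_sd_<measurement>`.
#'
#' @param path Path to the config file.
#' @return A [synthetic_config()] object.
#' @export
read_synthetic_config <- function(path) {
  kv <- .read_flat_config(path)
  num <- function(key, default = NULL) {
    if (!key %in% names(kv)) return(default)
    as.numeric(kv[[key]][[1]])
  }
  lst <- function(key, default = NULL) {
    if (!key %in% names(kv)) return(default) else kv[[key]][[1]]
  }
  measurements <- lst("measurements", cmn_measurements())
  grab <- function(prefix, meas) {
    out <- list()
    for (m in meas) {
      key <- paste0(prefix, m)
      if (key %in% names(kv)) out[[m]] <- as.numeric(kv[[key]][[1]])
    }
    if (length(out)) out else NULL
  }
  eff <- NULL
  if ("effect" %in% names(kv)) {
    eff <- do.call(rbind, lapply(kv[["effect"]], function(x) {
      if (length(x) != 4L)
        stopf("effect lines need 4 fields: measurement,roi_index,group,shift")
      data.frame(measurement = x[1], roi_index = as.integer(x[2]),
                 group = x[3], mean_shift = as.numeric(x[4]))
    }))
  }
  synthetic_config(
    n_group_a = num("n_group_a", 308), n_group_b = num("n_group_b", 390),
    n_rois = num("n_rois", 35), measurements = measurements,
    baseline_means = grab("baseline_mean_", measurements),
    baseline_sd = grab("baseline_sd_", measurements),
    injected_effects = eff,
    vertices_per_roi = num("vertices_per_roi"),
    hemispheres = lst("hemispheres", c("lh", "rh")),
    group_labels = lst("group_labels", c("A", "B")),
    seed = num("seed", 42))
}

# Parse `key = value` lines; repeated keys accumulate.  Values are split on
# commas; scalars stay length-1 character and are converted by callers.
.read_flat_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stopf("malformed config line (expected key = value): '%s'", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    kv[[key]] <- c(kv[[key]], list(parts))
  }
  kv
}
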