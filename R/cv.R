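#' Cross-validation scheme
#'
#' @param kind `"loo"` (leave-one-out) or `"kfold"`.  The convenience labels
#'   `"5fold"` and `"10fold"` are accepted and mapped to `kfold`.
#' @param n_folds Fold count for `kfold` (ignored for LOO).
#' @param stratified Stratify folds by group label (default TRUE; prevents
#'   single-class folds with imbalanced groups).
#' @param seed Integer seed controlling the fold assignment.
#' @return Object of class `cmn_cv_scheme`.
#' @export
cv_scheme <- function(kind = c("loo", "kfold", "5fold", "10fold"),
                      n_folds = NULL, stratified = TRUE, seed = 42L) {
  kind <- match.arg(kind)
  if (kind == "5fold") { kind <- "kfold"; n_folds <- n_folds %||% 5L }
  if (kind == "10fold") { kind <- "kfold"; n_folds <- n_folds %||% 10L }
  if (kind == "kfold") {
    if (!is_count(n_folds, 2)) stopf("kfold requires n_folds >= 2")
    n_folds <- as.integer(n_folds)
  } else n_folds <- NA_integer_
  structure(list(kind = kind, n_folds = n_folds,
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cmn_cv_scheme")
}

#' @export
format.cmn_cv_scheme <- function(x, ...) {
  if (x$kind == "loo") "loo" else sprintf("%dfold", x$n_folds)
}

#' @export
print.cmn_cv_scheme <- function(x, ...) {
  cat(sprintf("cmn_cv_scheme: %s (stratified=%s, seed=%d)\n", format(x),
              x$stratified, x$seed))
  invisible(x)
}

#' Deterministic fold assignment
#'
#' LOO yields one fold per subject.  For k-fold, subjects are shuffled
#' within class (when stratified) or globally, concatenated, and assigned to
#' folds cyclically by global position, so `n_folds = n` reproduces the LOO
#' partition exactly.
#'
#' @param labels Group labels (length n).
#' @param scheme A [cv_scheme()].
#' @return List of integer vectors of held-out (test) indices.
#' @export
make_folds <- function(labels, scheme) {
  n <- length(labels)
  if (scheme$kind == "loo") return(as.list(seq_len(n)))
  k <- scheme$n_folds
  if (k > n) stopf("n_folds (%d) exceeds the number of subjects (%d)", k, n)
  ord <- withr::with_seed(scheme$seed, {
    if (scheme$stratified) {
      unlist(lapply(split(seq_len(n), labels), sample), use.names = FALSE)
    } else sample.int(n)
  })
  fold_of <- rep_len(seq_len(k), n)
  unname(split(ord, fold_of))
}

# Per-fold inFS scores on training subjects only.  Returns features x folds
# matrix (restricted to `columns` when given).
.fold_infs_scores <- function(features, folds, params, columns = NULL) {
  cols <- columns %||% seq_len(ncol(features))
  vapply(folds, function(test) {
    Xtr <- features[-test, cols, drop = FALSE]
    infs_scores(feature_adjacency(Xtr, params), params$r)
  }, numeric(length(cols)))
}

# z-scoring helper: statistics from the training rows only
.scale_train <- function(Xtr) {
  mu <- colMeans(Xtr)
  sds <- apply(Xtr, 2, sd)
  sds[sds == 0] <- 1
  list(mu = mu, sd = sds,
       apply = function(X) sweep(sweep(X, 2, mu, "-"), 2, sds, "/"))
}

# Inner k-fold tuning of the SVM cost on the training subjects; pooled
# inner accuracy, ties broken towards the smallest cost.
.tune_cost <- function(Xtr, ytr, costs, inner_folds, seed) {
  sch <- cv_scheme("kfold", n_folds = min(inner_folds, min(table(ytr))),
                   stratified = TRUE, seed = seed)
  folds <- make_folds(ytr, sch)
  acc <- vapply(costs, function(C) {
    good <- 0L
    for (te in folds) {
      fit <- svm_linear(Xtr[-te, , drop = FALSE], ytr[-te], cost = C,
                        seed = seed)
      good <- good + sum(predict(fit, Xtr[te, , drop = FALSE]) == ytr[te])
    }
    good / length(ytr)
  }, numeric(1))
  costs[which.max(acc)]          # which.max takes the first (smallest) tie
}

#' Cross-validated classification with fold-wise feature selection
#'
#' For each outer fold the inFS ranking is computed on the training subjects
#' only, the top `K` features are selected, the SVM cost is tuned by an
#' inner stratified cross-validation on the training subjects, a linear SVM
#' is fit and the held-out subjects are predicted.  Accuracy is the pooled
#' fraction of correct held-out predictions.  Identical seeds reproduce
#' identical splits and results.
#'
#' @param features Subjects x n_f feature matrix.
#' @param labels Two-level group labels.
#' @param scheme A [cv_scheme()].
#' @param K Number of top-ranked features fed to the classifier (default
#'   100).
#' @param params [infs_params()] for the fold-wise ranking.
#' @param costs Margin-cost grid for nested tuning (log-spaced default).
#' @param columns Optional feature-column subset the whole procedure is
#'   restricted to (selection, tuning and fitting never see the excluded
#'   columns).
#' @param inner_folds Inner folds for cost tuning (default 5).
#' @param fold_scores Optional precomputed `.fold_infs_scores()` matrix.
#' @param measurement,hemisphere Optional context labels carried through to
#'   reports.
#' @return Object of class `cmn_cv_result`: `accuracy`, `predictions`,
#'   `labels`, `folds`, `per_fold` (top feature indices and scores, tuned
#'   cost per fold), `scheme`, `measurement`, `hemisphere`.
#' @export
run_cv <- function(features, labels, scheme, K = 100L,
                   params = infs_params(), costs = 10^(-3:3),
                   columns = NULL, inner_folds = 5L, fold_scores = NULL,
                   measurement = NULL, hemisphere = NULL) {
  features <- as.matrix(features)
  if (!is.factor(labels)) labels <- factor(labels)
  if (nlevels(labels) != 2) stopf("labels must have exactly two classes")
  if (length(labels) != nrow(features))
    stopf("labels length must match the number of subjects")
  cols <- columns %||% seq_len(ncol(features))
  if (!is_count(K, 1) || K > length(cols))
    stopf("K must be a positive integer <= the number of usable features (%d)",
          length(cols))
  if (any(table(labels) < 2)) stopf("each class needs >= 2 members")

  folds <- make_folds(labels, scheme)
  if (is.null(fold_scores))
    fold_scores <- .fold_infs_scores(features, folds, params, cols)
  stopifnot(ncol(fold_scores) == length(folds))

  pred <- factor(rep(levels(labels)[1], length(labels)),
                 levels = levels(labels))
  per_fold <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    ytr <- labels[-test]
    if (length(unique(ytr)) < 2)
      stopf("training fold %d contains a single class; use stratified folds",
            f)
    rk <- rank_features(fold_scores[, f])
    top <- rk$ranks[seq_len(K)]            # indices into `cols`
    sel <- cols[top]
    sc <- .scale_train(features[-test, sel, drop = FALSE])
    Xtr <- sc$apply(features[-test, sel, drop = FALSE])
    Xte <- sc$apply(features[test, sel, drop = FALSE])
    inner_seed <- scheme$seed + min(test)
    C <- .tune_cost(Xtr, ytr, costs, inner_folds, inner_seed)
    fit <- svm_linear(Xtr, ytr, cost = C, seed = inner_seed)
    pred[test] <- predict(fit, Xte)
    per_fold[[f]] <- list(top_features = sel,
                          scores = fold_scores[top, f],
                          tuned_cost = C)
  }
  structure(list(scheme = scheme,
                 measurement = measurement, hemisphere = hemisphere,
                 accuracy = mean(pred == labels),
                 predictions = pred, labels = labels, folds = folds,
                 per_fold = per_fold, K = as.integer(K), params = params),
            class = "cmn_cv_result")
}

#' @export
print.cmn_cv_result <- function(x, ...) {
  cat(sprintf("cmn_cv_result [%s%s]: accuracy %.3f over %d held-out predictions\n",
              format(x$scheme),
              if (is.null(x$measurement)) "" else
                paste0(", ", x$measurement, "/", x$hemisphere),
              x$accuracy, length(x$labels)))
  invisible(x)
}

#' Per-scheme feature weights for the reproducibility analysis
#'
#' A scheme's weight vector is the mean inFS score of each feature over the
#' scheme's outer training folds; its top set is the `k_f` highest-weight
#' features (ties broken by ascending feature index).
#'
#' @inheritParams run_cv
#' @param k_f Top-set size (default 5).
#' @return Object of class `cmn_scheme_ranking` with `weights`, `top_set`,
#'   `k_f`, `scheme`, `measurement`, `hemisphere`, `n_features`.
#' @export
scheme_ranking <- function(features, labels, scheme, params = infs_params(),
                           k_f = 5L, columns = NULL, fold_scores = NULL,
                           measurement = NULL, hemisphere = NULL) {
  features <- as.matrix(features)
  cols <- columns %||% seq_len(ncol(features))
  if (!is_count(k_f, 1) || k_f > length(cols))
    stopf("k_f must be a positive integer <= the number of features (%d)",
          length(cols))
  if (is.null(fold_scores)) {
    folds <- make_folds(labels, scheme)
    fold_scores <- .fold_infs_scores(features, folds, params, cols)
  }
  weights <- rowMeans(fold_scores)
  names(weights) <- colnames(features)[cols]
  top <- rank_features(weights)$ranks[seq_len(k_f)]
  structure(list(scheme = scheme, measurement = measurement,
                 hemisphere = hemisphere, weights = weights,
                 top_set = cols[top], k_f = as.integer(k_f),
                 n_features = ncol(features), columns = cols),
            class = "cmn_scheme_ranking")
}

#' Accuracy table averaged across cross-validation schemes
#'
#' One row per measurement x hemisphere; the reported accuracy is the
#' arithmetic mean of the scheme accuracies.  Every cell must carry the full
#' set of schemes, otherwise the missing combinations are listed in an
#' error.
#'
#' @param results List of [run_cv()] results with `measurement` and
#'   `hemisphere` set.
#' @return data.frame with per-scheme accuracy columns and `mean_accuracy`.
#' @export
accuracy_report <- function(results) {
  if (!length(results)) stopf("no results supplied")
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(measurement = r$measurement %||% NA_character_,
               hemisphere = r$hemisphere %||% NA_character_,
               scheme = format(r$scheme), accuracy = r$accuracy,
               stringsAsFactors = FALSE)
  }))
  if (anyNA(df$measurement) || anyNA(df$hemisphere))
    stopf("all results must carry measurement and hemisphere labels")
  schemes <- sort(unique(df$scheme))
  cells <- unique(df[c("measurement", "hemisphere")])
  missing <- character()
  for (i in seq_len(nrow(cells))) {
    have <- df$scheme[df$measurement == cells$measurement[i] &
                        df$hemisphere == cells$hemisphere[i]]
    lack <- setdiff(schemes, have)
    if (length(lack))
      missing <- c(missing, sprintf("%s/%s: %s", cells$measurement[i],
                                    cells$hemisphere[i],
                                    paste(lack, collapse = ",")))
  }
  if (length(missing))
    stopf("missing scheme results for: %s", paste(missing, collapse = "; "))
  out <- cells
  for (s in schemes)
    out[[s]] <- vapply(seq_len(nrow(cells)), function(i) {
      df$accuracy[df$measurement == cells$measurement[i] &
                    df$hemisphere == cells$hemisphere[i] & df$scheme == s]
    }, numeric(1))
  out$mean_accuracy <- rowMeans(out[, schemes, drop = FALSE])
  rownames(out) <- NULL
  out
}
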