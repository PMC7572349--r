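#' Linear support vector machine (L1-loss, dual coordinate descent)
#'
#' Max-margin linear classifier `sign(w'x + b)` fit by LIBLINEAR-style dual
#' coordinate descent with a bias term.  Deterministic given `seed` (the
#' per-epoch update order is a seeded permutation).
#'
#' @param x Numeric matrix of training samples (rows).
#' @param y Two-level factor (or vector coercible to one); the second level
#'   is the positive class.
#' @param cost Margin-cost hyperparameter C (> 0).
#' @param max_epochs Maximum passes over the data.
#' @param tol Convergence tolerance on the maximal projected gradient.
#' @param seed Integer seed for the update order.
#' @return Object of class `cmn_svm` with `w`, `b`, `levels`, `cost` and
#'   solver diagnostics (`primal_objective`, `dual_objective`, `converged`).
#' @export
svm_linear <- function(x, y, cost = 1, max_epochs = 1000L, tol = 1e-4,
                       seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.factor(y)) y <- factor(y)
  if (nlevels(y) != 2) stopf("y must have exactly two classes")
  if (length(y) != nrow(x)) stopf("length(y) must equal nrow(x)")
  if (any(table(y) == 0)) stopf("both classes must be present")
  ypm <- ifelse(as.integer(y) == 2L, 1, -1)
  fit <- .svm_dcd_fit(x, ypm, cost, 1.0, as.integer(max_epochs), tol,
                      as.integer(seed))
  structure(list(w = fit$w, b = fit$b, levels = levels(y), cost = cost,
                 converged = fit$converged, epochs = fit$epochs,
                 primal_objective = fit$primal_objective,
                 dual_objective = fit$dual_objective,
                 alpha = fit$alpha),
            class = "cmn_svm")
}

#' @param object A `cmn_svm` fit.
#' @param newdata Matrix of samples to predict.
#' @param type `"class"` for labels, `"decision"` for `w'x + b`.
#' @param ... Unused.
#' @rdname svm_linear
#' @export
predict.cmn_svm <- function(object, newdata, type = c("class", "decision"),
                            ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$w))
    stopf("newdata has %d columns, model expects %d", ncol(newdata),
          length(object$w))
  dec <- drop(newdata %*% object$w) + object$b
  if (type == "decision") return(dec)
  factor(object$levels[ifelse(dec >= 0, 2L, 1L)], levels = object$levels)
}
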