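#' Train an L2-regularized linear support vector machine
#'
#' Fits the linear SVM decision rule `sign(w'x + b)` by dual coordinate
#' descent on the L2-loss formulation (the algorithm of the LIBLINEAR
#' solver family).  The bias is obtained by augmenting the features with a
#' constant 1.  Training is deterministic given the data order, tolerance
#' and sweep cap.
#'
#' @param X numeric matrix, subjects in rows; no non-finite values.
#' @param y class labels with exactly two distinct values; the smaller
#'   (after `sort(unique(y))`) is encoded -1, the larger +1.
#' @param C penalty parameter (> 0).
#' @param tol solver tolerance on the maximal projected gradient.
#' @param max_sweeps cap on full passes over the data.
#' @return An object of class `linear_svm`: list with `w`, `b`, `C`,
#'   `levels` (the two class values, negative first).
#' @export
train_linear_svm <- function(X, y, C = 1, tol = 1e-3, max_sweeps = 1000L) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X contains non-finite values")
  lev <- sort(unique(y))
  if (length(lev) != 2L)
    stop("y must contain exactly two classes, got ", length(lev))
  if (!is.finite(C) || C <= 0) stop("C must be > 0")
  ypm <- ifelse(y == lev[2], 1, -1)
  fit <- svm_dcd(t(cbind(X, 1)), ypm, C, tol, as.integer(max_sweeps))
  w <- fit$w
  structure(list(w = w[-length(w)], b = w[length(w)], C = C, levels = lev,
                 sweeps = fit$sweeps),
            class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat("<linear_svm> ", length(x$w), " features, C = ", x$C,
      ", |w| in [", signif(min(abs(x$w)), 3), ", ",
      signif(max(abs(x$w)), 3), "], b = ", signif(x$b, 4), "\n", sep = "")
  invisible(x)
}

#' Predict classes with a trained linear SVM
#'
#' Decision rule `sign(w'x + b)`, with the boundary case `w'x + b = 0`
#' assigned to the positive class (`sign(0) = 1`).
#'
#' @param object a `linear_svm` fit.
#' @param newdata numeric matrix with the training feature columns.
#' @param ... unused.
#' @return vector of class labels on the scale of the training `y`.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  s <- as.vector(as.matrix(newdata) %*% object$w) + object$b
  ifelse(s >= 0, object$levels[2], object$levels[1])
}

#' Decision values `w'x + b`
#' @inheritParams predict.linear_svm
#' @return numeric vector of signed distances (unnormalized).
#' @export
decision_values <- function(object, newdata) {
  stopifnot(inherits(object, "linear_svm"))
  as.vector(as.matrix(newdata) %*% object$w) + object$b
}

#' 1-nearest-neighbour prediction
#'
#' Each test row receives the class of its nearest training row under the
#' Euclidean metric; distance ties go to the lower training-row index.
#'
#' @param train_X,train_y training features and labels.
#' @param test_X matrix of test rows.
#' @param K number of neighbours; only `K = 1` is supported.
#' @return vector of predicted labels.
#' @export
knn_predict <- function(train_X, train_y, test_X, K = 1L) {
  if (K != 1L) stop("only K = 1 is supported")
  train_X <- as.matrix(train_X); test_X <- as.matrix(test_X)
  if (nrow(train_X) == 0L) stop("empty training set")
  tn <- rowSums(train_X^2)
  # squared distances; which.min returns the first (= lowest-index) minimum
  D <- outer(rep(1, nrow(test_X)), tn) - 2 * test_X %*% t(train_X)
  nn <- apply(D, 1L, which.min)
  train_y[nn]
}
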