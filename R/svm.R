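# Soft-margin linear SVM: training (SMO on a precomputed Gram matrix),
# prediction, accuracy, and the data-driven default regularization constant.

#' Data-driven default regularization constant
#'
#' The reciprocal of the mean squared Euclidean norm of the training
#' examples, `C = 1 / mean(||x_i||^2)` — the classical SVMlight default for
#' a small, fixed, data-driven soft-margin constant. Scaling the data by a
#' factor `s` scales `C` by `s^-2`.
#'
#' @param X numeric matrix, examples x features.
#' @return positive scalar C.
#' @examples
#' defaultC(rbind(c(1, 0), c(1, 1), c(0, 1)))
#' @export
defaultC <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("X must be non-empty")
  msq <- mean(rowSums(X^2))
  if (msq <= 0) stop("cannot derive C from an all-zero matrix")
  1 / msq
}

# normalize labels to +/-1 with "action" (or the +1/TRUE level) positive
.as_y <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    if (!all(y %in% c("action", "non_action")))
      stop("character labels must be 'action'/'non_action'")
    y <- ifelse(y == "action", 1, -1)
  }
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be -1/+1")
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  y
}

# primal objective 1/2||w||^2 + C sum hinge at (w, b)
.primal_objective <- function(X, y, C, w, b) {
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (drop(X %*% w) + b)))
}

# train on a precomputed Gram matrix; returns alpha/bias/gap
.svm_solve_kernel <- function(K, y, C, tol = 1e-8) {
  smo_solve(K, y, C, tol = tol)
}

#' Train a soft-margin linear SVM
#'
#' Minimizes `1/2 ||w||^2 + C * sum_i max(0, 1 - y_i (w x_i + b))` with an
#' unpenalized bias, via sequential minimal optimization on the dual. The
#' solver is defined by this objective: the recorded `objective` slot is the
#' primal value at the solution and is the contract checked against an
#' independent quadratic-programming oracle in the test suite.
#'
#' @param X numeric matrix, examples x features. When `featureIdx` is given,
#'   `X` is interpreted as columns of a larger voxel space and subset first.
#' @param y labels: -1/+1 numerics, or `"action"`/`"non_action"` strings
#'   (action is the positive class). Both classes must be present.
#' @param C positive regularization constant; defaults to [defaultC()] of
#'   the (subset) training matrix.
#' @param featureIdx optional integer voxel indices naming the columns of
#'   `X` used for training and recorded in the model.
#' @param tol solver tolerance on the KKT gap.
#' @return a \linkS4class{LinearModel}.
#' @examples
#' X <- rbind(-1, 1); y <- c(-1, 1)
#' fit <- svmTrain(X, y, C = 100)
#' c(weight = fit@weights, bias = fit@bias)
#' @export
svmTrain <- function(X, y, C = NULL, featureIdx = NULL, tol = 1e-8) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("features must be finite")
  if (is.null(featureIdx)) featureIdx <- seq_len(ncol(X))
  else X <- X[, featureIdx, drop = FALSE]
  y <- .as_y(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (is.null(C)) C <- defaultC(X)
  fit <- .svm_solve_kernel(tcrossprod(X), y, C, tol = tol)
  w <- drop(crossprod(X, fit$alpha * y))
  new("LinearModel", weights = as.numeric(w), bias = fit$bias, cParam = C,
      objective = .primal_objective(X, y, C, w, fit$bias),
      featureIdx = as.integer(featureIdx))
}

#' Predict labels with a linear model
#'
#' The decision value of an example is `w . x + b`; its label is the sign,
#' with an exact zero resolved to the positive ("action") class.
#'
#' @param object a \linkS4class{LinearModel}.
#' @param newdata numeric matrix, examples x features: either over the full
#'   voxel space the model indexes into, or already restricted to exactly
#'   the model's feature set.
#' @param type `"class"` for -1/+1 labels, `"decision"` for raw decision
#'   values.
#' @param ... unused.
#' @return numeric vector of labels or decision values.
#' @export
setMethod("predict", "LinearModel",
  function(object, newdata, type = c("class", "decision"), ...) {
    type <- match.arg(type)
    newdata <- as.matrix(newdata)
    k <- length(object@featureIdx)
    if (ncol(newdata) == k) {
      Xs <- newdata
    } else if (ncol(newdata) >= max(object@featureIdx)) {
      Xs <- newdata[, object@featureIdx, drop = FALSE]
    } else {
      stop("newdata has ", ncol(newdata), " features; the model needs the ",
           k, " model features or the full voxel space")
    }
    d <- drop(Xs %*% object@weights) + object@bias
    if (type == "decision") d else ifelse(d >= 0, 1, -1)
  })

#' Classification accuracy
#'
#' @param predicted,truth label vectors of equal length (-1/+1 or
#'   `"action"`/`"non_action"`).
#' @return fraction of agreeing labels, in `[0, 1]`.
#' @export
accuracyScore <- function(predicted, truth) {
  p <- if (is.character(predicted) || is.factor(predicted))
    ifelse(as.character(predicted) == "action", 1, -1) else as.numeric(predicted)
  t <- if (is.character(truth) || is.factor(truth))
    ifelse(as.character(truth) == "action", 1, -1) else as.numeric(truth)
  if (length(p) != length(t)) stop("predicted and truth differ in length")
  mean(p == t)
}
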