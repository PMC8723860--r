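#' Kernel extreme learning machine
#'
#' Trains a kernel extreme learning machine: a single-hidden-layer network
#' whose output weights are solved in closed form in kernel space. With
#' one-hot targets `T` (N x C), Gram matrix `Omega[i, j] = K(x_i, x_j)` and
#' regularization coefficient `lambda > 0`, the coefficient matrix is
#'
#' \deqn{A = (I/\lambda + \Omega)^{-1} T}
#'
#' and new points score as `K(x, X_train) %*% A`. The system is symmetric
#' positive definite for any `lambda > 0`, so it is solved by Cholesky
#' factorization, never an explicit inverse. With the linear kernel this is
#' exactly dual ridge regression, which the test suite exploits as an
#' independent oracle.
#'
#' @param x numeric training matrix (N x d) or preprocessed [ckd_dataset()].
#' @param y training labels (factor); ignored when `x` is a dataset.
#' @param lambda regularization coefficient (> 0); larger values regularize
#'   *less* (the penalty is `I/lambda`).
#' @param kernel `"rbf"` (default), `"linear"` or `"polynomial"`.
#' @param gamma RBF/polynomial scale; default `1/d`.
#' @param degree,coef0 polynomial kernel parameters.
#' @return an object of class `kelm` with the stored training matrix, the
#'   solved coefficients `A` (N x C) and the kernel specification.
#' @examples
#' ds <- ckd_preprocess(ckd_synthesize(n_positive = 40, n_negative = 30,
#'                                     missing_rate = 0, seed = 1))$data
#' fit <- kelm(ds)
#' mean(predict(fit, ds$X) == ds$y)
#' @export
kelm <- function(x, y = NULL, lambda = 1,
                 kernel = c("rbf", "linear", "polynomial"),
                 gamma = NULL, degree = 3, coef0 = 1) {
  if (inherits(x, "ckd_dataset")) {
    y <- x$y
    x <- feature_matrix(x)
  }
  x <- as.matrix(x)
  y <- as.factor(y)
  stopifnot(nrow(x) >= 1, nrow(x) == length(y), lambda > 0)
  kernel <- match.arg(kernel)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  stopifnot(gamma > 0, degree >= 1)
  spec <- list(family = kernel, gamma = gamma, degree = degree, coef0 = coef0)
  Omega <- kernel_matrix(x, x, spec)
  if (!all(is.finite(Omega))) stop("non-finite kernel values")
  n <- nrow(x)
  Tm <- class_indicator(y)
  R <- tryCatch(chol(diag(n) / lambda + Omega),
                error = function(e) stop("kernel system is not positive definite: ",
                                         conditionMessage(e)))
  A <- backsolve(R, backsolve(R, Tm, transpose = TRUE))
  structure(list(X_train = x, A = A, lambda = lambda, kernel = spec,
                 classes = levels(y)),
            class = "kelm")
}

#' Predict from a kernel extreme learning machine
#'
#' @param object a fitted [kelm()] model.
#' @param newdata matrix of new rows (d columns) or preprocessed
#'   [ckd_dataset()].
#' @param type `"class"` (argmax score; ties break to the lower class
#'   index), `"score"` (raw per-class scores, the model's contribution to
#'   the fused feature vector) or `"prob"` (softmax of the scores).
#' @param ... unused.
#' @return factor, or an `N x C` matrix of scores/probabilities.
#' @export
predict.kelm <- function(object, newdata, type = c("class", "score", "prob"),
                         ...) {
  type <- match.arg(type)
  if (inherits(newdata, "ckd_dataset")) newdata <- feature_matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != ncol(object$X_train)) {
    stop("newdata has ", ncol(newdata), " columns; model was trained on ",
         ncol(object$X_train))
  }
  newdata <- matrix(as.numeric(newdata), ncol = ncol(object$X_train))
  scores <- kernel_matrix(newdata, object$X_train, object$kernel) %*% object$A
  colnames(scores) <- object$classes
  switch(type,
         score = scores,
         prob = softmax_rows(scores),
         class = factor(object$classes[max.col(scores, ties.method = "first")],
                        levels = object$classes))
}

#' Per-class score vector of a KELM model
#'
#' Returns the length-C score vector(s) a row contributes to the ensemble's
#' fused feature vector; identical to the corresponding rows of
#' `predict(object, x, type = "score")`.
#'
#' @param object a fitted [kelm()] model.
#' @param x one row, or a matrix of rows.
#' @return numeric matrix (rows x C).
#' @export
kelm_features <- function(object, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  predict(object, x, type = "score")
}

kernel_matrix <- function(X, Y, spec) {
  XY <- tcrossprod(X, Y)
  switch(spec$family,
         linear = XY,
         polynomial = (spec$gamma * XY + spec$coef0)^spec$degree,
         rbf = {
           sq <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * XY
           exp(-spec$gamma * pmax(sq, 0))
         })
}

class_indicator <- function(y) {
  Tm <- matrix(0, length(y), nlevels(y),
               dimnames = list(NULL, levels(y)))
  Tm[cbind(seq_along(y), as.integer(y))] <- 1
  Tm
}

softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}
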