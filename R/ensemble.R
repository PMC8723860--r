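#' Fuse per-model feature vectors
#'
#' Concatenates the three per-model contributions, in the fixed order
#' KELM, DBN, CNN-GRU, into the fused vector of width `q = n + m + l`.
#' Arguments are named to make an accidental permutation a visible error.
#'
#' @param f_kelm,f_dbn,f_cnn_gru numeric vectors, or matrices with aligned
#'   rows; none may be empty.
#' @return fused vector/matrix; the attribute `"widths"` records
#'   `c(n, m, l, q)`.
#' @examples
#' fuse_features(f_kelm = 1:2, f_dbn = 1:3, f_cnn_gru = 1:4)
#' @export
fuse_features <- function(f_kelm, f_dbn, f_cnn_gru) {
  parts <- list(f_kelm, f_dbn, f_cnn_gru)
  if (any(vapply(parts, function(p) length(p) == 0L, logical(1)))) {
    stop("every component of the fused vector must be non-empty")
  }
  if (any(vapply(parts, is.matrix, logical(1)))) {
    parts <- lapply(parts, function(p) if (is.matrix(p)) p else matrix(p, nrow = 1))
    widths <- vapply(parts, ncol, integer(1))
    out <- do.call(cbind, parts)
  } else {
    widths <- lengths(parts)
    out <- c(f_kelm, f_dbn, f_cnn_gru)
  }
  attr(out, "widths") <- c(n = widths[1], m = widths[2], l = widths[3],
                           q = sum(widths))
  out
}

#' Train the three-model ensemble
#'
#' Trains the kernel extreme learning machine, deep belief network and
#' CNN-GRU on the same (preprocessed, optionally rebalanced) training data.
#' At prediction time the three class posteriors are combined by weighted
#' soft voting (default), or a ridge-regularized logistic head fitted on
#' the fused feature vectors (`mode = "fused_head"`) produces the
#' posterior.
#'
#' @param x preprocessed [ckd_dataset()], or numeric matrix with `y`.
#' @param y labels when `x` is a matrix.
#' @param kelm_args,dbn_args,cnn_gru_args argument lists forwarded to the
#'   respective trainers.
#' @param mode `"soft_vote"` or `"fused_head"`.
#' @param weights soft-vote weights for (KELM, DBN, CNN-GRU); normalized
#'   internally.
#' @param seed base RNG seed; the three models train on derived seeds.
#' @return object of class `ckd_ensemble`.
#' @examples
#' ds <- ckd_preprocess(ckd_synthesize(n_positive = 60, n_negative = 40,
#'                                     missing_rate = 0, seed = 1))$data
#' ens <- train_ensemble(ds, dbn_args = list(hidden = c(8, 4),
#'                       epochs_pretrain = 2, epochs_finetune = 5),
#'                       cnn_gru_args = list(n_kernels = 3, gru_hidden = 6,
#'                       gru_output = 4, epochs = 5), seed = 9)
#' mean(predict(ens, ds) == ds$y)
#' @export
train_ensemble <- function(x, y = NULL, kelm_args = list(),
                           dbn_args = list(), cnn_gru_args = list(),
                           mode = c("soft_vote", "fused_head"),
                           weights = c(1, 1, 1) / 3, seed = NULL) {
  mode <- match.arg(mode)
  if (inherits(x, "ckd_dataset")) {
    y <- x$y
    x <- feature_matrix(x)
  }
  x <- as.matrix(x)
  y <- as.factor(y)
  stopifnot(length(weights) == 3, all(weights >= 0), sum(weights) > 0)
  base <- if (is.null(seed)) NULL else as.integer(seed)
  m_kelm <- do.call(kelm, c(list(x = x, y = y), kelm_args))
  m_dbn <- do.call(dbn, c(list(x = x, y = y,
                               seed = if (is.null(base)) NULL else base + 1L),
                          dbn_args))
  m_cnn <- do.call(cnn_gru, c(list(x = x, y = y,
                                   seed = if (is.null(base)) NULL else base + 2L),
                              cnn_gru_args))
  obj <- structure(list(kelm = m_kelm, dbn = m_dbn, cnn_gru = m_cnn,
                        mode = mode, weights = weights / sum(weights),
                        classes = levels(y), head = NULL),
                   class = "ckd_ensemble")
  if (mode == "fused_head") {
    fused <- ensemble_fused(obj, x)
    obj$head <- glmnet::glmnet(fused, y, family = "binomial", alpha = 0,
                               lambda = 0.01, standardize = TRUE)
  }
  obj
}

ensemble_fused <- function(obj, X) {
  fuse_features(f_kelm = kelm_features(obj$kelm, X),
                f_dbn = dbn_features(obj$dbn, X),
                f_cnn_gru = cnn_gru_features(obj$cnn_gru, X))
}

ensemble_posteriors <- function(obj, X) {
  list(kelm = softmax_rows(predict(obj$kelm, X, type = "score")),
       dbn = predict(obj$dbn, X, type = "prob"),
       cnn_gru = predict(obj$cnn_gru, X, type = "prob"))
}

#' Predict from the ensemble
#'
#' Soft voting averages the three per-model posteriors with the configured
#' weights (KELM scores pass through a softmax first); a tied binary vote
#' resolves to the positive (diseased) class, the clinically safe side.
#' `mode = "fused_head"` scores the fused feature vector with the trained
#' logistic head instead.
#'
#' @param object a [train_ensemble()] fit.
#' @param newdata matrix or preprocessed [ckd_dataset()].
#' @param type `"class"` or `"prob"`.
#' @param mode,weights override the training-time combination rule
#'   (`"fused_head"` requires the head to have been trained).
#' @param ... unused.
#' @export
predict.ckd_ensemble <- function(object, newdata, type = c("class", "prob"),
                                 mode = NULL, weights = NULL, ...) {
  type <- match.arg(type)
  mode <- mode %||% object$mode
  weights <- weights %||% object$weights
  if (inherits(newdata, "ckd_dataset")) newdata <- feature_matrix(newdata)
  if (mode == "fused_head") {
    if (is.null(object$head)) stop("fused head was not trained; refit with mode = 'fused_head'")
    fused <- ensemble_fused(object, newdata)
    p2 <- as.numeric(predict(object$head, newx = fused, type = "response"))
    prob <- cbind(1 - p2, p2)   # glmnet models P(second level)
    colnames(prob) <- object$classes
  } else {
    weights <- weights / sum(weights)
    ps <- ensemble_posteriors(object, newdata)
    prob <- weights[1] * ps$kelm + weights[2] * ps$dbn + weights[3] * ps$cnn_gru
    colnames(prob) <- object$classes
  }
  if (type == "prob") return(prob)
  # positive class is level 1; ties.method = "first" sends ties there
  factor(object$classes[max.col(prob, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.ckd_ensemble <- function(x, ...) {
  cat("<ckd_ensemble> KELM + DBN + CNN-GRU, mode =", x$mode, "\n")
  cat("  weights:", paste(fmt4(x$weights), collapse = " / "), "\n")
  invisible(x)
}
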