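#' Binary classification metrics
#'
#' Computes the confusion counts and the full metric suite used throughout
#' the package: sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' accuracy, precision `TP/(TP+FP)`, F-score (harmonic mean of precision
#' and sensitivity), Cohen's kappa `(p_o - p_e)/(1 - p_e)` with the chance
#' agreement `p_e` taken from the marginals, and (when scores are supplied)
#' the ROC AUC.
#'
#' @param y_true,y_pred factors over the same two levels; the positive
#'   (diseased) class defaults to the first level.
#' @param scores optional numeric score for the positive class (vector, or
#'   a posterior matrix whose column names include the positive level);
#'   enables the AUC.
#' @param positive positive class label.
#' @return a one-row `data.frame` of class `ckd_metrics` with columns
#'   `TP, FN, TN, FP, sensitivity, specificity, accuracy, precision,
#'   f_score, kappa, auc`. Undefined ratios (empty denominators) are `NA`.
#' @examples
#' compute_metrics(factor(c("ckd", "ckd", "notckd")),
#'                 factor(c("ckd", "notckd", "notckd")))
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL, positive = NULL) {
  y_true <- as.factor(y_true)
  y_pred <- factor(y_pred, levels = levels(y_true))
  if (is.null(positive)) positive <- levels(y_true)[1]
  stopifnot(positive %in% levels(y_true), length(y_true) == length(y_pred))
  is_pos <- y_true == positive
  pred_pos <- y_pred == positive
  out <- confusion_metrics(tp = sum(is_pos & pred_pos),
                           fn = sum(is_pos & !pred_pos),
                           tn = sum(!is_pos & !pred_pos),
                           fp = sum(!is_pos & pred_pos))
  if (!is.null(scores) && length(unique(is_pos)) == 2L) {
    if (is.matrix(scores)) scores <- scores[, positive]
    neg <- setdiff(levels(y_true), positive)[1]
    roc <- pROC::roc(response = y_true, predictor = as.numeric(scores),
                     levels = c(neg, positive), direction = "<",
                     quiet = TRUE)
    out$auc <- as.numeric(pROC::auc(roc))
  }
  out
}

#' Metrics from raw confusion counts
#'
#' The same metric formulas as [compute_metrics()], computed directly from
#' the four confusion-matrix cells (useful for re-deriving reported
#' per-run metrics from published confusion matrices).
#'
#' @param tp,fn,tn,fp confusion counts.
#' @return a one-row `ckd_metrics` data frame (`auc` is `NA`).
#' @examples
#' confusion_metrics(tp = 240, fn = 10, tn = 241, fp = 7)$sensitivity
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  n <- tp + fn + tn + fp
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  p_o <- (tp + tn) / n
  p_e <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else NA_real_
  structure(data.frame(TP = tp, FN = fn, TN = tn, FP = fp,
                       sensitivity = sens, specificity = spec,
                       accuracy = p_o, precision = prec, f_score = f1,
                       kappa = kappa, auc = NA_real_),
            class = c("ckd_metrics", "data.frame"))
}

#' Average rows of a metrics report
#'
#' Arithmetic column means of per-run metrics, the "Average" row of the
#' multi-run report.
#'
#' @param rows a data frame of per-run metrics (e.g. stacked
#'   [compute_metrics()] rows), or a numeric matrix.
#' @return a one-row data frame of column means (only numeric columns are
#'   averaged).
#' @examples
#' runs <- data.frame(sensitivity = c(0.96, 0.976, 0.976, 0.968, 0.96))
#' average_report(runs)
#' @export
average_report <- function(rows) {
  rows <- as.data.frame(rows)
  num <- vapply(rows, is.numeric, logical(1))
  out <- rows[1, , drop = FALSE]
  out[!num] <- NA
  out[num] <- lapply(rows[num], mean)
  rownames(out) <- "Average"
  out
}

# 4-decimal display convention (round-half-even via base round)
fmt4 <- function(x) {
  ifelse(is.na(x), "", formatC(round(x, 4), format = "f", digits = 4))
}
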