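#' Fit and apply leakage-free preprocessing
#'
#' Imputes missing cells, encodes categoricals numerically and min-max
#' scales every numeric column to `[0, 1]` (required downstream: the deep
#' belief network treats visible units as Bernoulli probabilities). The
#' fitted transform records per-column medians/modes, observed min/max and
#' level maps, so held-out data can be transformed with training statistics
#' only.
#'
#' Conventions: a constant numeric column scales to all zeros; values beyond
#' the training range are clipped into `[0, 1]`; binary categoricals map to
#' a single `{0, 1}` column (levels in sorted order), k-level categoricals to
#' one-hot columns; a level unseen at fit time encodes as the all-zero
#' ("other") row of its one-hot block (code 0 for binary columns), with a
#' message.
#'
#' @param ds a raw [ckd_dataset()].
#' @param numeric_impute `"median"` (default) or `"mean"`.
#' @param categorical_impute `"mode"` (the only supported strategy).
#' @param scaling `"minmax"` (the only supported strategy).
#' @param encoding `"onehot"` (the only supported strategy).
#' @return list with `data` (the preprocessed `ckd_dataset`, `X` now a
#'   numeric matrix in `[0, 1]`) and `transform` (a `ckd_transform` to apply
#'   to new data via [predict()][predict.ckd_transform]).
#' @examples
#' ds <- ckd_synthesize(n_positive = 30, n_negative = 20, seed = 1)
#' pp <- ckd_preprocess(ds)
#' range(pp$data$X)
#' @export
ckd_preprocess <- function(ds, numeric_impute = c("median", "mean"),
                           categorical_impute = "mode",
                           scaling = "minmax", encoding = "onehot") {
  stopifnot(inherits(ds, "ckd_dataset"))
  numeric_impute <- match.arg(numeric_impute)
  categorical_impute <- match.arg(categorical_impute, "mode")
  scaling <- match.arg(scaling, "minmax")
  encoding <- match.arg(encoding, "onehot")
  X <- as.data.frame(ds$X)
  columns <- list()
  for (nm in ds$schema$names) {
    col <- X[[nm]]
    if (ds$schema$kinds[[nm]] == "numeric") {
      obs <- col[!is.na(col)]
      if (!length(obs)) {
        stop("column '", nm, "' has no observed values; refusing to drop it silently")
      }
      fill <- if (numeric_impute == "median") median(obs) else mean(obs)
      columns[[nm]] <- list(kind = "numeric", impute = fill,
                            min = min(obs), max = max(obs))
    } else {
      obs <- as.character(col[!is.na(col)])
      if (!length(obs)) {
        stop("column '", nm, "' has no observed values; refusing to drop it silently")
      }
      tab <- table(obs)
      mode_lv <- names(tab)[which.max(tab)]   # ties: first in sorted order
      lev <- ds$schema$categories[[nm]] %||% sort(unique(obs))
      columns[[nm]] <- list(kind = "categorical", impute = mode_lv, levels = lev)
    }
  }
  tr <- structure(list(columns = columns,
                       config = list(numeric_impute = numeric_impute,
                                     categorical_impute = categorical_impute,
                                     scaling = scaling, encoding = encoding),
                       positive = ds$schema$positive,
                       negative = ds$schema$negative),
                  class = "ckd_transform")
  list(data = predict(tr, ds), transform = tr)
}

#' Apply a fitted preprocessing transform to new data
#'
#' @param object a `ckd_transform` from [ckd_preprocess()].
#' @param newdata a raw `ckd_dataset` with the same attributes the transform
#'   was fitted on.
#' @param ... unused.
#' @return the preprocessed `ckd_dataset` (numeric `X` in `[0, 1]`, no
#'   missing values).
#' @export
predict.ckd_transform <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "ckd_dataset"))
  X <- as.data.frame(newdata$X)
  missing_cols <- setdiff(names(object$columns), names(X))
  if (length(missing_cols)) {
    stop("newdata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- list()
  for (nm in names(object$columns)) {
    rec <- object$columns[[nm]]
    col <- X[[nm]]
    if (rec$kind == "numeric") {
      v <- as.numeric(col)
      v[is.na(v)] <- rec$impute
      rng <- rec$max - rec$min
      v <- if (rng > 0) (v - rec$min) / rng else rep(0, length(v))
      out[[nm]] <- pmin(pmax(v, 0), 1)
    } else {
      v <- as.character(col)
      v[is.na(v)] <- rec$impute
      unseen <- !(v %in% rec$levels)
      if (any(unseen)) {
        message(sum(unseen), " value(s) in '", nm,
                "' not seen at fit time; encoded as 'other' (all-zero code)")
      }
      if (length(rec$levels) <= 2L) {
        code <- as.numeric(v == rec$levels[min(2L, length(rec$levels))])
        code[unseen] <- 0
        out[[nm]] <- code
      } else {
        block <- vapply(rec$levels, function(lv) as.numeric(v == lv),
                        numeric(length(v)))
        block <- matrix(block, nrow = length(v),
                        dimnames = list(NULL, paste(nm, rec$levels, sep = ".")))
        block[unseen, ] <- 0
        out[[nm]] <- block
      }
    }
  }
  Xp <- do.call(cbind, lapply(names(out), function(nm) {
    b <- out[[nm]]
    if (is.matrix(b)) b else matrix(b, ncol = 1, dimnames = list(NULL, nm))
  }))
  schema <- infer_schema(Xp, object$positive, object$negative, processed = TRUE)
  structure(list(X = Xp, y = newdata$y, schema = schema,
                 provenance = paste0(newdata$provenance, " |preprocessed")),
            class = "ckd_dataset")
}

#' @export
print.ckd_transform <- function(x, ...) {
  cat(sprintf("<ckd_transform> %d columns (%s impute, %s scaling, %s encoding)\n",
              length(x$columns), x$config$numeric_impute, x$config$scaling,
              x$config$encoding))
  invisible(x)
}
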