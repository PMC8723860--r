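#' Construct a CKD-style tabular dataset
#'
#' The dataset object is the lingua franca of the package: a value table of
#' mixed numeric/categorical predictors (with `NA` as the explicit missing
#' marker), a binary diagnosis label, and a schema describing each attribute.
#' The positive (diseased) class is always the *first* factor level of the
#' label, so that every downstream tie-break ("lower class index" in the
#' classifiers, "positive on a tied vote" in the ensemble) favours detection.
#'
#' @param X data frame (raw data; factors/character for categorical columns)
#'   or numeric matrix (preprocessed data). Missing cells must be `NA`.
#' @param y class labels; coerced to a factor with levels
#'   `c(positive, negative)`.
#' @param positive,negative label of the diseased / healthy class.
#' @param provenance free-text tag recording where the data came from.
#' @param schema optional pre-built schema list; inferred from `X` when `NULL`.
#' @return An object of class `ckd_dataset`: a list with elements `X`, `y`,
#'   `schema` and `provenance`.
#' @examples
#' ds <- ckd_dataset(
#'   data.frame(age = c(48, NA, 62), rbc = factor(c("normal", "abnormal", NA))),
#'   y = c("ckd", "notckd", "ckd"))
#' ds
#' @export
ckd_dataset <- function(X, y, positive = "ckd", negative = "notckd",
                        provenance = "", schema = NULL) {
  if (is.matrix(X)) {
    storage.mode(X) <- "double"
  } else {
    X <- as.data.frame(X)
  }
  if (nrow(X) < 1L) stop("dataset must contain at least one row")
  if (length(y) != nrow(X)) stop("every row must have a label")
  y <- as.character(y)
  bad <- setdiff(unique(y[!is.na(y)]), c(positive, negative))
  if (length(bad) || anyNA(y)) {
    stop("unknown class level(s): ",
         paste(c(bad, if (anyNA(y)) "<missing>"), collapse = ", "),
         " (expected '", positive, "' or '", negative, "')")
  }
  y <- factor(y, levels = c(positive, negative))
  if (is.null(schema)) schema <- infer_schema(X, positive, negative)
  structure(list(X = X, y = y, schema = schema, provenance = provenance),
            class = "ckd_dataset")
}

# Schema: per-attribute kind tag plus admissible level sets for categoricals.
infer_schema <- function(X, positive, negative, processed = is.matrix(X)) {
  nm <- colnames(X)
  if (is.null(nm)) {
    nm <- sprintf("x%02d", seq_len(ncol(X)))
    colnames(X) <- nm
  }
  kinds <- vapply(seq_along(nm), function(j) {
    col <- if (is.data.frame(X)) X[[j]] else X[, j]
    if (is.numeric(col)) "numeric" else "categorical"
  }, character(1))
  names(kinds) <- nm
  categories <- list()
  for (j in which(kinds == "categorical")) {
    col <- X[[j]]
    lev <- if (is.factor(col)) levels(col) else sort(unique(as.character(col[!is.na(col)])))
    categories[[nm[j]]] <- lev
  }
  list(names = nm, kinds = kinds, categories = categories,
       positive = positive, negative = negative, processed = processed)
}

#' @export
print.ckd_dataset <- function(x, ...) {
  tab <- table(x$y)
  cat(sprintf("<ckd_dataset> %d rows x %d predictors (%s)\n",
              nrow(x$X), ncol(x$X),
              if (isTRUE(x$schema$processed)) "preprocessed" else "raw"))
  cat(sprintf("  classes: %s=%d, %s=%d\n",
              names(tab)[1], tab[1], names(tab)[2], tab[2]))
  n_num <- sum(x$schema$kinds == "numeric")
  cat(sprintf("  attributes: %d numeric, %d categorical; missing cells: %d\n",
              n_num, length(x$schema$kinds) - n_num, sum(is.na(as_table(x)))))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

# internal: X as something is.na() can scan uniformly
as_table <- function(ds) if (is.matrix(ds$X)) ds$X else as.matrix(ds$X)

#' Extract the numeric feature matrix of a preprocessed dataset
#'
#' @param ds a `ckd_dataset` whose predictors have been preprocessed (all
#'   numeric, no missing values), or a plain numeric matrix which is returned
#'   unchanged.
#' @return numeric matrix.
#' @export
feature_matrix <- function(ds) {
  if (is.matrix(ds)) return(ds)
  stopifnot(inherits(ds, "ckd_dataset"))
  if (!is.matrix(ds$X)) {
    stop("dataset is raw; run ckd_preprocess() first")
  }
  if (anyNA(ds$X)) stop("dataset still contains missing values")
  ds$X
}
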