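#' Read a CKD-style table from CSV or ARFF
#'
#' Reads a clinical table in either RFC-4180 CSV (header row required) or
#' ARFF, the format the public chronic-kidney-disease benchmark is
#' distributed in. `"?"` and empty cells become the missing marker `NA`;
#' leading/trailing whitespace around cell values (common in the public CKD
#' file) is stripped. The class column is located by name and its values
#' must be the positive/negative labels.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"arff"`.
#' @param class_col candidate class-column names, first match wins
#'   (case-insensitive).
#' @param positive,negative admissible class labels (default `"ckd"` /
#'   `"notckd"`).
#' @return a [ckd_dataset()] with missing markers preserved.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("age,rbc,class", "48,normal,ckd", "?,abnormal,ckd",
#'              "61,normal,notckd"), f)
#' read_ckd(f)
#' @export
read_ckd <- function(path, format = c("auto", "csv", "arff"),
                     class_col = c("class", "classification"),
                     positive = "ckd", negative = "notckd") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  df <- if (format == "csv") read_csv_strict(path) else read_arff_clean(path)
  cn <- tolower(names(df))
  hit <- which(cn %in% tolower(class_col))
  if (!length(hit)) {
    stop("schema error: no class column found (looked for: ",
         paste(class_col, collapse = ", "), ")")
  }
  hit <- hit[1]
  y <- trimws(as.character(df[[hit]]))
  y[y == ""] <- NA
  X <- df[, -hit, drop = FALSE]
  # categorical columns as factors over their observed levels
  for (j in seq_along(X)) {
    if (!is.numeric(X[[j]])) {
      v <- trimws(as.character(X[[j]]))
      v[v %in% c("", "?")] <- NA
      X[[j]] <- factor(v)
    }
  }
  ckd_dataset(X, y, positive = positive, negative = negative,
              provenance = path)
}

# CSV dialect checks: consistent field counts, so a mangled line is reported
# by number instead of silently recycling.
read_csv_strict <- function(path) {
  nf <- count.fields(path, sep = ",", quote = "\"", blank.lines.skip = TRUE)
  if (length(nf) < 2L) stop("format error: ", path, " has no data rows")
  bad <- which(nf != nf[1])
  if (length(bad)) {
    stop(sprintf("format error: line %d of %s has %d fields (header has %d)",
                 bad[1], path, nf[bad[1]], nf[1]))
  }
  df <- read.csv(path, na.strings = c("?", ""), strip.white = TRUE,
                 stringsAsFactors = FALSE, check.names = FALSE)
  type.convert(df, as.is = TRUE, na.strings = c("?", ""))
}

read_arff_clean <- function(path) {
  df <- tryCatch(foreign::read.arff(path),
                 error = function(e) stop("format error: ", conditionMessage(e)))
  for (j in seq_along(df)) {
    if (is.factor(df[[j]])) {
      lv <- trimws(levels(df[[j]]))
      levels(df[[j]]) <- ifelse(lv == "?", NA, lv)
    }
  }
  df
}

#' Write a CKD-style table to CSV or ARFF
#'
#' The inverse of [read_ckd()]: missing cells are written as `"?"`, the label
#' goes into a `class` column, and a round trip preserves cell values and
#' missing markers.
#'
#' @param ds a [ckd_dataset()] (raw or preprocessed).
#' @param path output file path.
#' @param format `"auto"` (by extension), `"csv"` or `"arff"`.
#' @return `path`, invisibly.
#' @export
write_ckd <- function(ds, path, format = c("auto", "csv", "arff")) {
  stopifnot(inherits(ds, "ckd_dataset"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  df <- as.data.frame(ds$X)
  df$class <- ds$y
  if (format == "csv") {
    write.table(df, path, sep = ",", na = "?", quote = FALSE,
                row.names = FALSE)
  } else {
    foreign::write.arff(df, path)
  }
  invisible(path)
}
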