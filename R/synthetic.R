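#' Generate a seeded synthetic CKD-like dataset
#'
#' Emulates the statistical shape of the public chronic-kidney-disease
#' benchmark table so that the package builds and tests without any
#' download: class-conditional numeric features (unit variance, class means
#' separated by `class_separation`), categorical features with
#' class-dependent level probabilities, configurable class imbalance
#' (default 250 diseased : 150 healthy) and independent cell-wise
#' missingness over the predictors. The same parameters and seed reproduce
#' the dataset bit for bit.
#'
#' Every third categorical feature has three levels (`low`/`normal`/`high`,
#' probabilities 0.15/0.35/0.50 for the diseased class, reversed for the
#' healthy class); the rest are binary (`no`/`yes`, P(yes) 0.7 vs 0.3).
#'
#' @param n_positive,n_negative class sample counts.
#' @param d_numeric,d_categorical feature counts.
#' @param class_separation standardized shift between class-conditional
#'   numeric means (>= 0).
#' @param missing_rate probability that a predictor cell is masked, in
#'   `[0, 1)`. Labels are never masked.
#' @param positive,negative class label names.
#' @param seed RNG seed (the caller's RNG state is left untouched).
#' @return a raw [ckd_dataset()].
#' @examples
#' ds <- ckd_synthesize(seed = 7)
#' table(ds$y)
#' @export
ckd_synthesize <- function(n_positive = 250, n_negative = 150,
                           d_numeric = 11, d_categorical = 13,
                           class_separation = 2.5, missing_rate = 0.1,
                           positive = "ckd", negative = "notckd",
                           seed = NULL) {
  stopifnot(n_positive >= 0, n_negative >= 0, n_positive + n_negative >= 1,
            d_numeric >= 0, d_categorical >= 0, d_numeric + d_categorical >= 1,
            class_separation >= 0, missing_rate >= 0, missing_rate < 1)
  n <- n_positive + n_negative
  y <- c(rep(positive, n_positive), rep(negative, n_negative))
  is_pos <- y == positive
  with_seed_or_not(seed, {
    X <- list()
    if (d_numeric > 0) {
      for (j in seq_len(d_numeric)) {
        mu <- ifelse(is_pos, class_separation, 0)
        X[[sprintf("num_%02d", j)]] <- rnorm(n, mean = mu, sd = 1)
      }
    }
    if (d_categorical > 0) {
      for (j in seq_len(d_categorical)) {
        if (j %% 3L == 0L) {
          lev <- c("low", "normal", "high")
          pr_pos <- c(0.15, 0.35, 0.50)
          pr_neg <- rev(pr_pos)
        } else {
          lev <- c("no", "yes")
          pr_pos <- c(0.3, 0.7)
          pr_neg <- c(0.7, 0.3)
        }
        v <- character(n)
        v[is_pos] <- sample(lev, sum(is_pos), replace = TRUE, prob = pr_pos)
        v[!is_pos] <- sample(lev, sum(!is_pos), replace = TRUE, prob = pr_neg)
        X[[sprintf("cat_%02d", j)]] <- factor(v, levels = lev)
      }
    }
    X <- as.data.frame(X)
    if (missing_rate > 0) {
      mask <- matrix(runif(n * ncol(X)) < missing_rate, nrow = n)
      for (j in seq_along(X)) X[[j]][mask[, j]] <- NA
    }
    ckd_dataset(X, y, positive = positive, negative = negative,
                provenance = sprintf(
                  "synthetic(n+=%d, n-=%d, sep=%g, miss=%g, seed=%s)",
                  n_positive, n_negative, class_separation, missing_rate,
                  if (is.null(seed)) "NULL" else seed))
  })
}

#' Stratified data splitting
#'
#' Holdout or k-fold partitions with per-class proportions within one sample
#' of the global proportions; partitions are disjoint and exhaustive.
#'
#' @param y label factor, or a [ckd_dataset()].
#' @param scheme `"holdout"` or `"kfold"`.
#' @param fraction held-out fraction for `"holdout"` (default 0.25).
#' @param k fold count for `"kfold"` (default 5); every class must have at
#'   least `k` members.
#' @param seed RNG seed.
#' @return for `"holdout"`, `list(train =, test =)` of row indices; for
#'   `"kfold"`, a list of `k` disjoint test-index vectors.
#' @examples
#' ds <- ckd_synthesize(n_positive = 20, n_negative = 10, seed = 1)
#' stratified_split(ds, "holdout", fraction = 0.3, seed = 2)
#' @export
stratified_split <- function(y, scheme = c("holdout", "kfold"),
                             fraction = 0.25, k = 5, seed = NULL) {
  if (inherits(y, "ckd_dataset")) y <- y$y
  y <- as.factor(y)
  scheme <- match.arg(scheme)
  with_seed_or_not(seed, {
    if (scheme == "holdout") {
      stopifnot(fraction > 0, fraction < 1)
      test <- integer(0)
      for (lv in levels(y)) {
        idx <- which(y == lv)
        n_test <- round(fraction * length(idx))
        test <- c(test, sample(idx, n_test))
      }
      test <- sort(test)
      list(train = setdiff(seq_along(y), test), test = test)
    } else {
      stopifnot(k >= 2)
      counts <- table(y)
      if (any(counts < k)) {
        stop("class '", names(counts)[which.min(counts)], "' has only ",
             min(counts), " members; cannot form ", k, " folds")
      }
      fold_of <- integer(length(y))
      for (lv in levels(y)) {
        idx <- sample(which(y == lv))
        fold_of[idx] <- rep_len(seq_len(k), length(idx))
      }
      lapply(seq_len(k), function(f) which(fold_of == f))
    }
  })
}
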