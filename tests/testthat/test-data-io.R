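test_that("CSV parsing preserves rows, missing markers and types", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,rbc,class",
               "48,normal,ckd",
               "?,abnormal,ckd",
               "61,normal,notckd"), f)
  ds <- read_ckd(f)
  expect_s3_class(ds, "ckd_dataset")
  expect_equal(nrow(ds$X), 3)
  expect_equal(sum(is.na(as.matrix(ds$X))), 1)
  expect_true(is.numeric(ds$X$age))
  expect_equal(as.character(ds$schema$kinds), c("numeric", "categorical"))
  expect_equal(table(ds$y)[["ckd"]], 2)
})

test_that("unknown class levels and malformed files raise informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,class", "48,ckd", "50,maybe"), f)
  expect_error(read_ckd(f), "unknown class level.*maybe")

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,rbc,class", "48,normal,ckd", "50,ckd"), g)
  expect_error(read_ckd(g), "format error: line 3")

  h <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,rbc", "48,normal"), h)
  expect_error(read_ckd(h), "no class column")
})

test_that("CSV and ARFF round trips preserve values and missing markers", {
  ds <- ckd_synthesize(n_positive = 15, n_negative = 10, missing_rate = 0.15,
                       seed = 42)
  for (ext in c(".csv", ".arff")) {
    f <- withr::local_tempfile(fileext = ext)
    write_ckd(ds, f)
    back <- read_ckd(f)
    expect_equal(nrow(back$X), nrow(ds$X))
    expect_equal(is.na(as.matrix(back$X)), is.na(as.matrix(ds$X)),
                 ignore_attr = TRUE)
    num <- names(which(ds$schema$kinds == "numeric"))
    for (nm in num) expect_equal(back$X[[nm]], ds$X[[nm]], tolerance = 1e-8)
    cat_cols <- setdiff(ds$schema$names, num)
    for (nm in cat_cols) {
      expect_equal(as.character(back$X[[nm]]), as.character(ds$X[[nm]]))
    }
    expect_equal(as.character(back$y), as.character(ds$y))
  }
})

test_that("preprocessing imputes, scales to [0,1] and encodes as documented", {
  X <- data.frame(lab = c(1, NA, 3),
                  flow = c(0, 5, 10),
                  flat = c(7, 7, 7),
                  yn = factor(c("no", "yes", NA)),
                  tri = factor(c("a", "b", "c")))
  ds <- ckd_dataset(X, c("ckd", "ckd", "notckd"))
  pp <- ckd_preprocess(ds)
  M <- pp$data$X
  # median of {1,3} = 2, then min-max over observed range [1,3]
  expect_equal(M[, "lab"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(M[, "flow"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(M[, "flat"], c(0, 0, 0), ignore_attr = TRUE)  # constant -> 0
  # binary -> single {0,1} column; missing filled with the mode ("no")
  expect_equal(M[, "yn"], c(0, 1, 0), ignore_attr = TRUE)
  expect_equal(colnames(M)[4:7], c("yn", "tri.a", "tri.b", "tri.c"))
  expect_true(all(M >= 0 & M <= 1) && !anyNA(M))
})

test_that("transforms apply training statistics to new data, clipping overflow", {
  tr_ds <- ckd_dataset(data.frame(v = c(0, 5, 10)), c("ckd", "ckd", "notckd"))
  pp <- ckd_preprocess(tr_ds)
  new_ds <- ckd_dataset(data.frame(v = c(-5, 5, 20)), c("ckd", "ckd", "notckd"))
  out <- predict(pp$transform, new_ds)
  expect_equal(out$X[, "v"], c(0, 0.5, 1), ignore_attr = TRUE)

  unseen <- ckd_dataset(data.frame(yn = factor(c("maybe", "no"))),
                        c("ckd", "notckd"))
  fit_ds <- ckd_dataset(data.frame(yn = factor(c("no", "yes"))),
                        c("ckd", "notckd"))
  tr <- ckd_preprocess(fit_ds)$transform
  expect_message(out2 <- predict(tr, unseen), "not seen at fit")
  expect_equal(out2$X[, "yn"], c(0, 0), ignore_attr = TRUE)
})

test_that("all-missing columns are refused rather than silently dropped", {
  ds <- ckd_dataset(data.frame(a = c(NA_real_, NA_real_), b = c(1, 2)),
                    c("ckd", "notckd"))
  expect_error(ckd_preprocess(ds), "no observed values")
})

test_that("preprocessing is idempotent on already-preprocessed data", {
  pp1 <- ckd_preprocess(ckd_synthesize(n_positive = 40, n_negative = 30,
                                       seed = 5))
  pp2 <- ckd_preprocess(pp1$data)
  expect_equal(pp2$data$X, pp1$data$X, tolerance = 1e-12)
})

test_that("synthetic generator hits exact counts, determinism and missingness", {
  ds <- ckd_synthesize(seed = 3)
  expect_equal(as.integer(table(ds$y)), c(250, 150))
  ds2 <- ckd_synthesize(seed = 3)
  expect_identical(ds, ds2)
  expect_false(identical(ds, ckd_synthesize(seed = 4)))
  # labels never masked
  expect_false(anyNA(ds$y))
  # observed missing fraction within the 99% binomial interval around 0.1
  n_cells <- prod(dim(as.matrix(ds$X)))
  miss <- sum(is.na(as.matrix(ds$X))) / n_cells
  ci <- qbinom(c(0.005, 0.995), n_cells, 0.1) / n_cells
  expect_gte(miss, ci[1])
  expect_lte(miss, ci[2])
})

test_that("class-conditional mean difference converges to class_separation", {
  ds <- ckd_synthesize(n_positive = 5000, n_negative = 5000, d_numeric = 4,
                       d_categorical = 0, class_separation = 1.7,
                       missing_rate = 0, seed = 8)
  pos <- ds$y == "ckd"
  se <- sqrt(1 / sum(pos) + 1 / sum(!pos))
  for (j in 1:4) {
    diff_j <- mean(ds$X[pos, j]) - mean(ds$X[!pos, j])
    expect_lt(abs(diff_j - 1.7), 3 * se)
  }
})

test_that("stratified splits preserve class balance and cover every row", {
  ds <- ckd_synthesize(seed = 2)
  folds <- stratified_split(ds, "kfold", k = 5, seed = 1)
  for (f in folds) {
    expect_equal(sum(ds$y[f] == "ckd"), 50)
    expect_equal(sum(ds$y[f] == "notckd"), 30)
  }
  expect_equal(sort(unlist(folds)), 1:400)

  s1 <- stratified_split(ds, "holdout", fraction = 0.25, seed = 9)
  s2 <- stratified_split(ds, "holdout", fraction = 0.25, seed = 9)
  expect_identical(s1, s2)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_equal(sort(c(s1$train, s1$test)), 1:400)

  tiny <- factor(rep(c("ckd", "notckd"), c(3, 50)), levels = c("ckd", "notckd"))
  expect_error(stratified_split(tiny, "kfold", k = 5), "only 3 members")
})
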