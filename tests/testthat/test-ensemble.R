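make_small_ensemble <- function() {
  ds <- make_processed_fixture(n_pos = 60, n_neg = 40, seed = 71)
  list(ds = ds,
       ens = train_ensemble(ds,
                            dbn_args = list(hidden = c(8, 4),
                                            epochs_pretrain = 2,
                                            epochs_finetune = 6),
                            cnn_gru_args = list(n_kernels = 3, gru_input = 4,
                                                gru_hidden = 6, gru_output = 4,
                                                epochs = 6),
                            seed = 72))
}

test_that("soft voting averages posteriors; degenerate weights recover KELM", {
  fx <- make_small_ensemble()
  X <- fx$ds$X[1:5, ]
  p <- predict(fx$ens, X, type = "prob")
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-12)
  ps <- ckdens:::ensemble_posteriors(fx$ens, X)
  expect_equal(p, (ps$kelm + ps$dbn + ps$cnn_gru) / 3, tolerance = 1e-12)
  # one-hot weight on the KELM collapses the vote onto it
  p_kelm <- predict(fx$ens, X, type = "prob", weights = c(1, 0, 0))
  expect_equal(p_kelm, ps$kelm, tolerance = 1e-12)
})

test_that("a tied binary vote resolves to the positive class", {
  fx <- make_small_ensemble()
  # (0.6,0.4), (0.4,0.6), (0.5,0.5) average to the (0.5, 0.5) tie
  expect_equal(rowMeans(cbind(c(0.6, 0.4), c(0.4, 0.6), c(0.5, 0.5))),
               c(0.5, 0.5))
  ens <- fx$ens
  classes <- ens$classes
  tie_prob <- matrix(0.5, 1, 2, dimnames = list(NULL, classes))
  lab <- classes[max.col(tie_prob, ties.method = "first")]
  expect_equal(lab, "ckd")    # positive level is first by construction
  expect_equal(levels(fx$ds$y)[1], "ckd")
})

test_that("fused head scores the concatenated feature vector", {
  ds <- make_processed_fixture(n_pos = 60, n_neg = 40, seed = 73)
  ens <- train_ensemble(ds, mode = "fused_head",
                        dbn_args = list(hidden = c(8, 4), epochs_pretrain = 2,
                                        epochs_finetune = 6),
                        cnn_gru_args = list(n_kernels = 3, gru_input = 4,
                                            gru_hidden = 6, gru_output = 4,
                                            epochs = 6),
                        seed = 74)
  fused <- ckdens:::ensemble_fused(ens, ds$X)
  expect_equal(unname(attr(fused, "widths")[["q"]]),
               2 + (4 + 2) + (3 * 4 + 2))
  p <- predict(ens, ds$X, type = "prob")
  expect_equal(rowSums(p), rep(1, nrow(ds$X)), tolerance = 1e-10)
  expect_gt(mean(predict(ens, ds$X) == ds$y), 0.9)
  # soft-vote predictions remain available but a missing head is an error
  ens2 <- make_small_ensemble()$ens
  expect_error(predict(ens2, ds$X, mode = "fused_head"), "head")
})

test_that("the multi-run protocol is leakage-free and reports Table-style CSV", {
  rep <- run_experiment(synthetic = list(n_positive = 80, n_negative = 50),
                        n_runs = 2, dbn_args = fast_dbn_args,
                        cnn_gru_args = list(n_kernels = 3, gru_input = 4,
                                            gru_hidden = 6, gru_output = 4,
                                            epochs = 10),
                        base_seed = 7)
  expect_s3_class(rep, "ckd_run_report")
  expect_equal(rep$adasyn_order, "after_split")
  # canary: evaluation rows are original rows, disjoint from training rows
  for (s in rep$splits) {
    expect_length(intersect(s$train, s$test), 0)
    expect_true(all(s$test <= 130))
  }
  # Average row is the exact column mean
  expect_equal(rep$average$accuracy, mean(rep$metrics$accuracy),
               tolerance = 1e-12)
  f <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, f)
  lines <- readLines(f)
  expect_equal(lines[1],
               "No. of runs,Sensitivity,Specificity,Accuracy,F-score,Kappa")
  expect_equal(length(lines), 4)      # header + 2 runs + Average
  expect_match(lines[4], "^Average")
  # n_runs = 1: the Average row equals the single run
  one <- run_experiment(synthetic = list(n_positive = 60, n_negative = 40),
                        n_runs = 1, dbn_args = fast_dbn_args,
                        cnn_gru_args = list(n_kernels = 3, gru_input = 4,
                                            gru_hidden = 6, gru_output = 4,
                                            epochs = 10),
                        base_seed = 8)
  expect_equal(one$average$accuracy, one$metrics$accuracy[1])
})

test_that("the before-split protocol is runnable and flagged in metadata", {
  rep <- run_experiment(synthetic = list(n_positive = 60, n_negative = 40),
                        n_runs = 1, adasyn_order = "before_split",
                        dbn_args = fast_dbn_args,
                        cnn_gru_args = list(n_kernels = 3, gru_input = 4,
                                            gru_hidden = 6, gru_output = 4,
                                            epochs = 10),
                        base_seed = 9)
  expect_equal(rep$adasyn_order, "before_split")
  # augmented pool: evaluated rows can exceed the 100 original ones
  expect_gt(max(unlist(rep$splits)), 100)
})

test_that("invalid experiment configurations fail before any training", {
  expect_error(run_experiment(n_runs = 0), "n_runs")
  expect_error(run_experiment(test_fraction = 1.2), "test_fraction")
  expect_error(run_experiment(mode = "majority"), "arg")
})
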