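test_that("valid 1-D cross-correlation matches hand-computed windows", {
  # delta kernel picks out the centred slice
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(conv1d(x, c(0, 0, 1, 0, 0), activation = "identity"), x[3:6])
  expect_equal(conv1d(1:6, rep(1, 5), activation = "identity"), c(15, 20))
  out <- conv1d(rnorm(10), rnorm(5))
  expect_length(out, 6)
  expect_true(all(out > 0 & out < 1))    # sigmoid range
  expect_error(conv1d(1:3, rep(1, 5)), "shorter")
})

test_that("average pooling windows, constants and remainders behave", {
  expect_equal(avg_pool1d(c(1, 3, 5, 7), 2), c(2, 6))
  expect_equal(avg_pool1d(rep(4.2, 6), 3), rep(4.2, 2))
  expect_message(out <- avg_pool1d(c(1, 2, 3), 2), "discarding 1")
  expect_equal(out, 1.5)
})

test_that("conv/pool output lengths hold for all input lengths 5..64", {
  for (n in 5:64) {
    x <- seq_len(n) / n
    cv <- conv1d(x, rep(0.2, 5), activation = "identity")
    expect_length(cv, n - 4)
    if (length(cv) >= 2) {
      pooled <- suppressMessages(avg_pool1d(cv, 2))
      expect_length(pooled, (n - 4) %/% 2)
    }
  }
})

test_that("a GRU step follows the gate algebra", {
  H <- 3
  zero_w <- list(Wz = matrix(0, H, H + 2), Wr = matrix(0, H, H + 2),
                 Wh = matrix(0, H, H + 2))
  h_prev <- c(0.4, -0.2, 0.8)
  # zero weights: z = r = 0.5, candidate = tanh(0) = 0, h' = 0.5 h
  expect_equal(gru_step(h_prev, c(1, 2), zero_w), 0.5 * h_prev)
  # z forced to ~0 keeps the previous state
  keep_w <- zero_w
  keep_w$Wz <- matrix(-30, H, H + 2)
  expect_equal(gru_step(h_prev, c(1, 1), keep_w), h_prev, tolerance = 1e-10)
  # with h_prev in [-1, 1] the new state is a convex mix of bounded terms
  set.seed(31)
  for (r in 1:20) {
    w <- list(Wz = matrix(rnorm(H * (H + 2), sd = 2), H),
              Wr = matrix(rnorm(H * (H + 2), sd = 2), H),
              Wh = matrix(rnorm(H * (H + 2), sd = 2), H))
    h0 <- runif(H, -1, 1)
    h1 <- gru_step(h0, rnorm(2), w)
    expect_true(all(abs(h1) <= pmax(abs(h0), 1) + 1e-12))
  }
  expect_error(gru_step(h_prev, c(1, 2, 3), zero_w), "chain")
})

test_that("softmax output is a shift-invariant probability vector", {
  expect_equal(softmax_prob(c(2, 2, 2)), rep(1 / 3, 3))
  expect_equal(softmax_prob(log(c(1, 3))), c(0.25, 0.75))
  z <- c(0.3, -1.2, 4)
  expect_equal(softmax_prob(z), softmax_prob(z + 17), tolerance = 1e-12)
  expect_equal(sum(softmax_prob(z)), 1, tolerance = 1e-12)
})

test_that("the batched forward pass matches a step-by-step manual trace", {
  # 6 features, 1 conv map (k=3), pool 2 -> map length 2, one GRU step
  cfg <- list(d = 6, k = 3, J = 1, K = 2, I = 2, H = 2, O = 2, C = 2,
              L1 = 4, L2 = 2, Tsteps = 1)
  params <- withr::with_seed(32, ckdens:::init_cnn_gru(cfg))
  x <- c(0.9, 0.1, 0.4, 0.7, 0.2, 0.5)
  # manual trace with the exported primitives
  smap <- conv1d(x, params$Kmat[, 1], bias = params$bconv[1])
  pooled <- avg_pool1d(smap, 2)
  u <- params$units[[1]]
  h1 <- gru_step(c(0, 0), pooled, list(Wz = u$Wz, Wr = u$Wr, Wh = u$Wh))
  o <- tanh(as.vector(u$Wo %*% h1) + u$bo)
  post <- softmax_prob(as.vector(params$Ws %*% o) + params$bs)
  fw <- ckdens:::cnn_gru_forward(params, cfg, matrix(x, 1, 6))
  expect_equal(as.vector(fw$pbar), post, tolerance = 1e-12)
})

test_that("analytic gradients match central differences on a <=50-param model", {
  cfg <- list(d = 6, k = 3, J = 1, K = 2, I = 2, H = 2, O = 2, C = 2,
              L1 = 4, L2 = 2, Tsteps = 1)
  params <- withr::with_seed(33, ckdens:::init_cnn_gru(cfg))
  set.seed(34)
  X <- matrix(runif(3 * 6), 3, 6)
  Y <- t(ckdens:::class_indicator(factor(c("a", "b", "a"))))
  g <- ckdens:::cnn_gru_grad(params, cfg, X, Y)
  theta <- ckdens:::flatten_cnn_params(params)
  expect_lte(length(theta), 50)
  analytic <- ckdens:::flatten_cnn_params(g$grads)
  eps <- 1e-6
  numeric_g <- vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (ckdens:::cnn_gru_grad(ckdens:::unflatten_cnn_params(tp, params),
                           cfg, X, Y)$loss -
       ckdens:::cnn_gru_grad(ckdens:::unflatten_cnn_params(tm, params),
                             cfg, X, Y)$loss) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(analytic - numeric_g)) / max(abs(numeric_g)), 1e-4)
})

test_that("training separates the synthetic classes; zero epochs does not", {
  ds <- ckd_preprocess(ckd_synthesize(n_positive = 180, n_negative = 120,
                                      class_separation = 3, missing_rate = 0,
                                      seed = 35))$data
  fit <- cnn_gru(ds, n_kernels = 6, gru_input = 8, gru_hidden = 16,
                 gru_output = 4, lr = 0.8, epochs = 50, seed = 36)
  acc_trained <- mean(predict(fit, ds$X) == ds$y)
  expect_gte(acc_trained, 0.95)
  raw <- cnn_gru(ds, n_kernels = 6, gru_input = 8, gru_hidden = 16,
                 gru_output = 4, epochs = 0, seed = 36)
  expect_lt(mean(predict(raw, ds$X) == ds$y), acc_trained - 0.15)
  refit <- cnn_gru(ds, n_kernels = 6, gru_input = 8, gru_hidden = 16,
                   gru_output = 4, lr = 0.8, epochs = 50, seed = 36)
  expect_identical(fit, refit)
})

test_that("posteriors and fusion features have the documented shape", {
  ds <- make_processed_fixture(n_pos = 30, n_neg = 20, seed = 37)
  fit <- cnn_gru(ds, n_kernels = 3, gru_input = 4, gru_hidden = 5,
                 gru_output = 4, epochs = 3, seed = 38)
  p <- predict(fit, ds$X[1:4, ], type = "prob")
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-12)
  fv <- cnn_gru_features(fit, ds$X[1:4, ])
  expect_equal(ncol(fv), 3 * 4 + 2)
  expect_identical(fv, cnn_gru_features(fit, ds$X[1:4, ]))
})
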