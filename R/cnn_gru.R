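#' 1-D convolution, pooling, GRU and softmax primitives
#'
#' Building blocks of the hybrid convolutional/recurrent classifier.
#' `conv1d()` is a valid (no-padding) 1-D cross-correlation:
#' `out[m] = sum_w kernel[w] * x[m + w - 1] + bias`, output length
#' `length(x) - k + 1`, optionally passed through the sigmoid. `avg_pool1d()`
#' averages non-overlapping windows of the given width, discarding any
#' trailing remainder with a notice. `gru_step()` advances one gated
#' recurrent unit step:
#' \deqn{z = \sigma(W_z [h, x]), \quad r = \sigma(W_r [h, x]),}
#' \deqn{\tilde h = \tanh(W [r \odot h, x]), \quad
#'       h' = (1 - z) \odot h + z \odot \tilde h.}
#' `softmax_prob()` maps logits to a probability vector (shift-invariant,
#' sums to 1).
#'
#' @param x numeric input vector (or input slice for `gru_step()`).
#' @param kernel convolution kernel.
#' @param bias scalar bias.
#' @param activation `"sigmoid"` (default, as in the network) or
#'   `"identity"`.
#' @return numeric vector.
#' @examples
#' conv1d(1:6, rep(1, 5), activation = "identity")  # 15 20
#' avg_pool1d(c(1, 3, 5, 7), 2)                     # 2 6
#' softmax_prob(log(c(1, 3)))                       # 0.25 0.75
#' @export
conv1d <- function(x, kernel, bias = 0, activation = c("sigmoid", "identity")) {
  activation <- match.arg(activation)
  k <- length(kernel)
  if (length(x) < k) stop("input shorter than the convolution kernel")
  L <- length(x) - k + 1L
  out <- vapply(seq_len(L), function(m) sum(kernel * x[m:(m + k - 1L)]),
                numeric(1)) + bias
  if (activation == "sigmoid") plogis(out) else out
}

#' @rdname conv1d
#' @param width pooling window width.
#' @export
avg_pool1d <- function(x, width = 2) {
  stopifnot(width >= 1)
  L <- length(x) %/% width
  if (L < 1L) stop("input shorter than the pooling window")
  rem <- length(x) %% width
  if (rem > 0) {
    message("avg_pool1d: discarding ", rem, " trailing value(s)")
  }
  colMeans(matrix(x[seq_len(L * width)], nrow = width))
}

#' @rdname conv1d
#' @param h_prev previous hidden state.
#' @param weights list with gate matrices `Wz` (update), `Wr` (reset) and
#'   `Wh` (candidate), each `H x (H + I)`.
#' @export
gru_step <- function(h_prev, x, weights) {
  H <- length(h_prev)
  u <- c(h_prev, x)
  if (ncol(weights$Wz) != length(u)) stop("GRU weight shapes do not chain")
  z <- plogis(as.vector(weights$Wz %*% u))
  r <- plogis(as.vector(weights$Wr %*% u))
  cand <- tanh(as.vector(weights$Wh %*% c(r * h_prev, x)))
  (1 - z) * h_prev + z * cand
}

#' @rdname conv1d
#' @param logits numeric logit vector.
#' @export
softmax_prob <- function(logits) {
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Train the hybrid CNN-GRU classifier
#'
#' A 1-D convolutional feature extractor feeding a bank of gated recurrent
#' units. Each of the `n_kernels` sigmoid convolution maps (valid
#' cross-correlation, width `kernel_width`) is average-pooled
#' (width `pool_width`), chunked into slices of `gru_input` values
#' (zero-padded final chunk) and consumed stepwise by its own GRU. Each
#' unit's final hidden state passes through a tanh layer of `gru_output`
#' units (the penultimate representation) and a shared softmax head; the
#' network posterior is the mean of the per-unit posteriors (a soft vote
#' across the GRU bank). Training minimizes cross-entropy by stochastic
#' gradient descent with analytic backpropagation through the whole stack.
#'
#' @param x numeric training matrix or preprocessed [ckd_dataset()]; the
#'   row length must be at least `kernel_width`.
#' @param y labels; ignored when `x` is a dataset.
#' @param n_kernels number of convolution maps / GRU units (default 12).
#' @param kernel_width convolution kernel width (default 5).
#' @param pool_width average-pooling width (default 2).
#' @param gru_input,gru_hidden,gru_output per-unit GRU sizes
#'   (defaults 25 / 50 / 10).
#' @param lr learning rate (default 0.5; the mean posterior across the GRU
#'   bank scales per-unit gradients down by the unit count, so steps larger
#'   than typical single-network rates are appropriate); `epochs` epoch
#'   count (0 leaves the random initialization untouched); `batch_size`
#'   minibatch size.
#' @param epochs,batch_size see above.
#' @param seed RNG seed; fixed seed gives a bit-identical model.
#' @return an object of class `cnn_gru` with the parameters, configuration
#'   and per-epoch `history` (loss, accuracy).
#' @examples
#' ds <- ckd_preprocess(ckd_synthesize(n_positive = 60, n_negative = 40,
#'                                     missing_rate = 0, seed = 1))$data
#' fit <- cnn_gru(ds, n_kernels = 3, gru_hidden = 6, gru_output = 4,
#'                epochs = 5, seed = 2)
#' mean(predict(fit, ds$X) == ds$y)
#' @export
cnn_gru <- function(x, y = NULL, n_kernels = 12, kernel_width = 5,
                    pool_width = 2, gru_input = 25, gru_hidden = 50,
                    gru_output = 10, lr = 0.5, epochs = 40,
                    batch_size = 32, seed = NULL) {
  if (inherits(x, "ckd_dataset")) {
    y <- x$y
    x <- feature_matrix(x)
  }
  x <- as.matrix(x)
  y <- as.factor(y)
  stopifnot(n_kernels >= 1, kernel_width >= 1, pool_width >= 1,
            gru_input >= 1, gru_hidden >= 1, gru_output >= 1,
            lr > 0, epochs >= 0, batch_size >= 1)
  if (ncol(x) < kernel_width) stop("input shorter than the convolution kernel")
  L1 <- ncol(x) - kernel_width + 1L
  L2 <- L1 %/% pool_width
  if (L2 < 1L) stop("pooled feature map would be empty; reduce pool_width")
  cfg <- list(d = ncol(x), k = kernel_width, J = n_kernels, K = pool_width,
              I = gru_input, H = gru_hidden, O = gru_output,
              C = nlevels(y), L1 = L1, L2 = L2,
              Tsteps = max(1L, ceiling(L2 / gru_input)))
  with_seed_or_not(seed, {
    params <- init_cnn_gru(cfg)
    model <- structure(list(params = params, config = cfg,
                            classes = levels(y), history = NULL),
                       class = "cnn_gru")
    if (epochs == 0) return(model)
    Y <- t(class_indicator(y))              # C x N
    hist <- data.frame(epoch = seq_len(epochs), loss = NA_real_,
                       accuracy = NA_real_)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(x))
      for (batch in split_batches(ord, batch_size)) {
        g <- cnn_gru_grad(model$params, cfg, x[batch, , drop = FALSE],
                          Y[, batch, drop = FALSE])
        model$params <- sgd_step(model$params, g$grads, lr)
      }
      fw <- cnn_gru_forward(model$params, cfg, x)
      pred <- max.col(t(fw$pbar), ties.method = "first")
      hist$loss[ep] <- ce_loss(fw$pbar, Y)
      hist$accuracy[ep] <- mean(pred == as.integer(y))
    }
    model$history <- hist
    model
  })
}

init_cnn_gru <- function(cfg) {
  gi <- function(nr, nc) matrix(rnorm(nr * nc, sd = 1 / sqrt(nc)), nr, nc)
  list(
    Kmat = matrix(rnorm(cfg$k * cfg$J, sd = 1 / sqrt(cfg$k)), cfg$k, cfg$J),
    bconv = numeric(cfg$J),
    units = lapply(seq_len(cfg$J), function(j) {
      list(Wz = gi(cfg$H, cfg$H + cfg$I),
           Wr = gi(cfg$H, cfg$H + cfg$I),
           Wh = gi(cfg$H, cfg$H + cfg$I),
           Wo = gi(cfg$O, cfg$H), bo = numeric(cfg$O))
    }),
    Ws = gi(cfg$C, cfg$O), bs = numeric(cfg$C))
}

sgd_step <- function(p, g, lr) {
  p$Kmat <- p$Kmat - lr * g$Kmat
  p$bconv <- p$bconv - lr * g$bconv
  for (j in seq_along(p$units)) {
    for (nm in c("Wz", "Wr", "Wh", "Wo", "bo")) {
      p$units[[j]][[nm]] <- p$units[[j]][[nm]] - lr * g$units[[j]][[nm]]
    }
  }
  p$Ws <- p$Ws - lr * g$Ws
  p$bs <- p$bs - lr * g$bs
  p
}

ce_loss <- function(pbar, Y) {
  -mean(log(pmax(colSums(pbar * Y), 1e-12)))
}

# im2col: (B*L1) x k sliding-window matrix; row (m-1)*B + b holds
# X[b, m:(m+k-1)]
im2col <- function(X, k, L1) {
  M <- matrix(0, nrow(X) * L1, k)
  for (w in seq_len(k)) M[, w] <- as.vector(X[, w + seq_len(L1) - 1L])
  M
}

# batched forward pass; columns = samples throughout the recurrent part
cnn_gru_forward <- function(params, cfg, X, keep_cache = FALSE) {
  B <- nrow(X)
  M <- im2col(X, cfg$k, cfg$L1)
  Craw <- sweep(M %*% params$Kmat, 2, params$bconv, "+")
  S <- plogis(Craw)                         # (B*L1) x J
  cache <- if (keep_cache) list(M = M, S = S) else NULL
  posts <- vector("list", cfg$J)
  pool_idx <- lapply(seq_len(cfg$L2), function(t) (t - 1L) * cfg$K + seq_len(cfg$K))
  for (j in seq_len(cfg$J)) {
    Sj <- matrix(S[, j], B, cfg$L1)
    P <- vapply(pool_idx, function(ix) rowMeans(Sj[, ix, drop = FALSE]),
                numeric(B))
    P <- matrix(P, nrow = B, ncol = cfg$L2) # B x L2
    u <- params$units[[j]]
    h <- matrix(0, cfg$H, B)
    steps <- vector("list", cfg$Tsteps)
    for (t in seq_len(cfg$Tsteps)) {
      xt <- seq_chunk(P, t, cfg$I)          # I x B
      U <- rbind(h, xt)
      z <- plogis(u$Wz %*% U)
      r <- plogis(u$Wr %*% U)
      V <- rbind(r * h, xt)
      hc <- tanh(u$Wh %*% V)
      h_new <- (1 - z) * h + z * hc
      steps[[t]] <- list(h_prev = h, xt = xt, U = U, z = z, r = r,
                         V = V, hc = hc)
      h <- h_new
    }
    O <- tanh(sweep(u$Wo %*% h, 1, u$bo, "+"))
    logit <- sweep(params$Ws %*% O, 1, params$bs, "+")
    post <- apply(logit, 2, softmax_prob)
    if (is.null(dim(post))) post <- matrix(post, nrow = cfg$C)
    posts[[j]] <- post
    if (keep_cache) {
      cache$units[[j]] <- list(P = P, steps = steps, hT = h, O = O,
                               post = post)
    }
  }
  pbar <- Reduce(`+`, posts) / cfg$J        # C x B
  list(pbar = pbar, posts = posts, cache = cache)
}

# t-th zero-padded slice of the pooled map, as an I x B matrix
seq_chunk <- function(P, t, I) {
  cols <- (t - 1L) * I + seq_len(I)
  out <- matrix(0, I, nrow(P))
  keep <- cols <= ncol(P)
  if (any(keep)) out[keep, ] <- t(P[, cols[keep], drop = FALSE])
  out
}

# loss + analytic gradients for a batch; Y is C x B one-hot
cnn_gru_grad <- function(params, cfg, X, Y) {
  B <- nrow(X)
  fw <- cnn_gru_forward(params, cfg, X, keep_cache = TRUE)
  loss <- ce_loss(fw$pbar, Y)
  grads <- zero_like(params)
  dpbar <- -(Y / pmax(fw$pbar, 1e-12)) / B  # d(mean CE)/d pbar
  dS_all <- matrix(0, B * cfg$L1, cfg$J)
  for (j in seq_len(cfg$J)) {
    cj <- fw$cache$units[[j]]
    u <- params$units[[j]]
    dpost <- dpbar / cfg$J
    post <- cj$post
    dlogit <- post * sweep(dpost, 2, colSums(dpost * post), "-")
    grads$Ws <- grads$Ws + tcrossprod(dlogit, cj$O)
    grads$bs <- grads$bs + rowSums(dlogit)
    dO <- crossprod(params$Ws, dlogit) * (1 - cj$O^2)
    grads$units[[j]]$Wo <- tcrossprod(dO, cj$hT)
    grads$units[[j]]$bo <- rowSums(dO)
    dh <- crossprod(u$Wo, dO)
    dxt <- vector("list", cfg$Tsteps)
    for (t in rev(seq_len(cfg$Tsteps))) {
      st <- fw$cache$units[[j]]$steps[[t]]
      dz <- dh * (st$hc - st$h_prev)
      dhc <- dh * st$z
      dh_prev <- dh * (1 - st$z)
      dac <- dhc * (1 - st$hc^2)
      grads$units[[j]]$Wh <- grads$units[[j]]$Wh + tcrossprod(dac, st$V)
      dV <- crossprod(u$Wh, dac)
      dvh <- dV[seq_len(cfg$H), , drop = FALSE]
      dx <- dV[cfg$H + seq_len(cfg$I), , drop = FALSE]
      dr <- dvh * st$h_prev
      dh_prev <- dh_prev + dvh * st$r
      daz <- dz * st$z * (1 - st$z)
      grads$units[[j]]$Wz <- grads$units[[j]]$Wz + tcrossprod(daz, st$U)
      dU <- crossprod(u$Wz, daz)
      dh_prev <- dh_prev + dU[seq_len(cfg$H), , drop = FALSE]
      dx <- dx + dU[cfg$H + seq_len(cfg$I), , drop = FALSE]
      dar <- dr * st$r * (1 - st$r)
      grads$units[[j]]$Wr <- grads$units[[j]]$Wr + tcrossprod(dar, st$U)
      dU <- crossprod(u$Wr, dar)
      dh_prev <- dh_prev + dU[seq_len(cfg$H), , drop = FALSE]
      dx <- dx + dU[cfg$H + seq_len(cfg$I), , drop = FALSE]
      dxt[[t]] <- dx
      dh <- dh_prev
    }
    # gradient into the pooled map, dropping the zero padding
    dP <- matrix(0, B, cfg$L2)
    for (t in seq_len(cfg$Tsteps)) {
      cols <- (t - 1L) * cfg$I + seq_len(cfg$I)
      keep <- cols <= cfg$L2
      if (any(keep)) dP[, cols[keep]] <- t(dxt[[t]][keep, , drop = FALSE])
    }
    # average-pool backward: spread dP/K over each window
    dSj <- matrix(0, B, cfg$L1)
    for (t in seq_len(cfg$L2)) {
      ix <- (t - 1L) * cfg$K + seq_len(cfg$K)
      dSj[, ix] <- dSj[, ix] + dP[, t] / cfg$K
    }
    dS_all[, j] <- as.vector(dSj)
  }
  dC <- dS_all * fw$cache$S * (1 - fw$cache$S)
  grads$Kmat <- crossprod(fw$cache$M, dC)
  grads$bconv <- colSums(dC)
  list(loss = loss, grads = grads)
}

zero_like <- function(p) {
  z <- p
  z$Kmat[] <- 0; z$bconv[] <- 0; z$Ws[] <- 0; z$bs[] <- 0
  for (j in seq_along(z$units)) {
    for (nm in c("Wz", "Wr", "Wh", "Wo", "bo")) z$units[[j]][[nm]][] <- 0
  }
  z
}

# flatten/unflatten parameters (used by the finite-difference checks)
flatten_cnn_params <- function(p) {
  c(as.vector(p$Kmat), p$bconv,
    unlist(lapply(p$units, function(u) {
      c(as.vector(u$Wz), as.vector(u$Wr), as.vector(u$Wh),
        as.vector(u$Wo), u$bo)
    })),
    as.vector(p$Ws), p$bs)
}

unflatten_cnn_params <- function(theta, template) {
  take <- local({
    pos <- 0L
    function(ref) {
      n <- length(ref)
      out <- theta[pos + seq_len(n)]
      pos <<- pos + n
      if (is.matrix(ref)) matrix(out, nrow(ref), ncol(ref)) else out
    }
  })
  p <- template
  p$Kmat <- take(template$Kmat)
  p$bconv <- take(template$bconv)
  for (j in seq_along(p$units)) {
    for (nm in c("Wz", "Wr", "Wh", "Wo", "bo")) {
      p$units[[j]][[nm]] <- take(template$units[[j]][[nm]])
    }
  }
  p$Ws <- take(template$Ws)
  p$bs <- take(template$bs)
  p
}

#' Predict from a CNN-GRU model
#'
#' @param object a fitted [cnn_gru()] model.
#' @param newdata matrix or preprocessed [ckd_dataset()].
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @export
predict.cnn_gru <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "ckd_dataset")) newdata <- feature_matrix(newdata)
  newdata <- matrix(as.numeric(newdata), ncol = object$config$d)
  pbar <- t(cnn_gru_forward(object$params, object$config, newdata)$pbar)
  colnames(pbar) <- object$classes
  if (type == "prob") pbar
  else factor(object$classes[max.col(pbar, ties.method = "first")],
              levels = object$classes)
}

#' CNN-GRU feature vector for ensemble fusion
#'
#' Per-unit penultimate (tanh) representations concatenated across the GRU
#' bank, followed by the mean posterior; length `J * gru_output + C` per
#' row.
#'
#' @param object a fitted [cnn_gru()] model.
#' @param x one row or a matrix of rows.
#' @return numeric matrix.
#' @export
cnn_gru_features <- function(object, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- matrix(as.numeric(x), ncol = object$config$d)
  fw <- cnn_gru_forward(object$params, object$config, x, keep_cache = TRUE)
  feats <- do.call(cbind, lapply(fw$cache$units, function(u) t(u$O)))
  cbind(feats, t(fw$pbar))
}
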