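#' Restricted Boltzmann machine primitives
#'
#' An RBM is a bipartite energy-based model over binary visible units `v`
#' (length `n_v`) and hidden units `h` (length `n_h`) with parameters
#' `w` (`n_v x n_h` weights), `a` (visible biases) and `b` (hidden biases):
#'
#' \deqn{E(v, h) = -\sum_i a_i v_i - \sum_j b_j h_j - \sum_{ij} v_i w_{ij} h_j}
#'
#' The joint is `P(v, h) = exp(-E) / Z` with `Z` the sum of `exp(-E)` over
#' all states, and the conditionals factorize into sigmoids:
#' `P(h_j = 1 | v) = sigmoid(b_j + sum_i w_ij v_i)` and symmetrically for
#' the visible units.
#'
#' @param n_v,n_h layer sizes.
#' @param sd standard deviation of the Gaussian weight initialization.
#' @param seed RNG seed.
#' @return `rbm_init()` returns a parameter list with elements `w`, `a`, `b`.
#' @name rbm
NULL

#' @rdname rbm
#' @export
rbm_init <- function(n_v, n_h, sd = 0.01, seed = NULL) {
  with_seed_or_not(seed, {
    list(w = matrix(rnorm(n_v * n_h, sd = sd), n_v, n_h),
         a = numeric(n_v), b = numeric(n_h))
  })
}

#' @rdname rbm
#' @param v visible state: a vector of length `n_v` (values in `[0, 1]`), or
#'   for the conditional-probability functions a matrix with `n_v` columns
#'   (rows = samples).
#' @param h hidden state: vector of length `n_h`, or matrix with `n_h`
#'   columns.
#' @param params RBM parameter list (`w`, `a`, `b`).
#' @export
rbm_energy <- function(v, h, params) {
  v <- as.numeric(v); h <- as.numeric(h)
  if (length(v) != nrow(params$w) || length(h) != ncol(params$w)) {
    stop("state lengths do not match RBM shape")
  }
  -(sum(params$a * v) + sum(params$b * h) +
      as.numeric(t(v) %*% params$w %*% h))
}

#' @rdname rbm
#' @export
rbm_hidden_prob <- function(v, params) {
  if (is.matrix(v)) {
    if (ncol(v) != nrow(params$w)) stop("visible width mismatch")
    plogis(sweep(v %*% params$w, 2, params$b, "+"))
  } else {
    if (length(v) != nrow(params$w)) stop("visible length mismatch")
    plogis(params$b + as.vector(crossprod(params$w, v)))
  }
}

#' @rdname rbm
#' @export
rbm_visible_prob <- function(h, params) {
  if (is.matrix(h)) {
    if (ncol(h) != ncol(params$w)) stop("hidden width mismatch")
    plogis(sweep(tcrossprod(h, params$w), 2, params$a, "+"))
  } else {
    if (length(h) != ncol(params$w)) stop("hidden length mismatch")
    plogis(params$a + as.vector(params$w %*% h))
  }
}

#' One contrastive-divergence update
#'
#' Performs a single CD-k gradient step on a minibatch: positive statistics
#' from the data, negative statistics from `k` alternating Gibbs
#' half-steps (hidden states sampled, visible states propagated as
#' probabilities, the standard low-variance recipe). With `lr = 0` the
#' parameters are returned unchanged.
#'
#' @param params RBM parameter list.
#' @param batch minibatch matrix (rows = samples, values in `[0, 1]`).
#' @param lr learning rate.
#' @param cd_steps `k` in CD-k (default 1).
#' @param seed RNG seed; when `NULL` the current RNG stream is consumed.
#' @return updated parameter list; attribute `"recon_error"` carries the
#'   mean squared reconstruction error of the batch.
#' @export
rbm_cd_update <- function(params, batch, lr = 0.1, cd_steps = 1, seed = NULL) {
  batch <- as.matrix(batch)
  stopifnot(ncol(batch) == nrow(params$w), cd_steps >= 1,
            all(batch >= 0 & batch <= 1))
  with_seed_or_not(seed, {
    B <- nrow(batch)
    ph0 <- rbm_hidden_prob(batch, params)
    h <- matrix(runif(length(ph0)) < ph0, nrow = B) * 1
    v <- batch
    ph <- ph0
    for (s in seq_len(cd_steps)) {
      v <- rbm_visible_prob(h, params)
      ph <- rbm_hidden_prob(v, params)
      if (s < cd_steps) h <- matrix(runif(length(ph)) < ph, nrow = B) * 1
    }
    out <- list(
      w = params$w + lr * (crossprod(batch, ph0) - crossprod(v, ph)) / B,
      a = params$a + lr * colMeans(batch - v),
      b = params$b + lr * colMeans(ph0 - ph))
    attr(out, "recon_error") <- mean((batch - v)^2)
    out
  })
}

#' Train a deep belief network
#'
#' Greedy layer-wise pretraining of stacked RBMs by contrastive divergence
#' (each layer is trained on the previous layer's hidden probabilities, not
#' samples), followed by supervised fine-tuning: a softmax head is fitted on
#' the frozen top-layer features (multinomial logistic regression with a
#' small weight decay, to stay finite on separable data), then the whole
#' stack plus head is refined by plain stochastic gradient descent on the
#' cross-entropy loss. With `epochs_finetune = 0` only the head is trained
#' on frozen features.
#'
#' @param x numeric matrix with values in `[0, 1]` (visible units are
#'   treated as Bernoulli probabilities), or a preprocessed
#'   [ckd_dataset()].
#' @param y labels; ignored when `x` is a dataset.
#' @param hidden hidden layer sizes, e.g. `c(32, 16)`.
#' @param lr_pretrain,lr_finetune learning rates.
#' @param epochs_pretrain,epochs_finetune epoch counts (each >= 0).
#' @param cd_steps `k` in CD-k.
#' @param batch_size minibatch size.
#' @param seed RNG seed; fixed seed gives a bit-identical model.
#' @return an object of class `dbn` with the RBM stack (`layers`), the
#'   softmax `head`, the class levels and a per-epoch training `history`.
#' @examples
#' ds <- ckd_preprocess(ckd_synthesize(n_positive = 60, n_negative = 40,
#'                                     missing_rate = 0, seed = 1))$data
#' fit <- dbn(ds, hidden = c(8, 4), epochs_pretrain = 2,
#'            epochs_finetune = 5, seed = 2)
#' mean(predict(fit, ds$X) == ds$y)
#' @export
dbn <- function(x, y = NULL, hidden = c(32, 16),
                lr_pretrain = 0.1, lr_finetune = 0.1,
                epochs_pretrain = 10, epochs_finetune = 30,
                cd_steps = 1, batch_size = 32, seed = NULL) {
  if (inherits(x, "ckd_dataset")) {
    y <- x$y
    x <- feature_matrix(x)
  }
  x <- as.matrix(x)
  y <- as.factor(y)
  stopifnot(length(hidden) >= 1, all(hidden >= 1), cd_steps >= 1,
            lr_pretrain > 0, lr_finetune > 0,
            epochs_pretrain >= 0, epochs_finetune >= 0, batch_size >= 1)
  if (min(x) < -1e-8 || max(x) > 1 + 1e-8) {
    stop("DBN inputs must lie in [0, 1]; preprocess the data first")
  }
  n <- nrow(x)
  with_seed_or_not(seed, {
    sizes <- c(ncol(x), hidden)
    layers <- list()
    up <- x
    for (l in seq_along(hidden)) {
      p <- rbm_init(sizes[l], sizes[l + 1], sd = 0.01)
      for (ep in seq_len(epochs_pretrain)) {
        ord <- sample.int(nrow(up))
        for (batch in split_batches(ord, batch_size)) {
          p <- rbm_cd_update(p, up[batch, , drop = FALSE], lr = lr_pretrain,
                             cd_steps = cd_steps)
        }
      }
      layers[[l]] <- p
      up <- rbm_hidden_prob(up, p)  # probabilities, not samples
    }
    model <- list(layers = layers, head = NULL, classes = levels(y),
                  sizes = sizes, history = NULL)
    class(model) <- "dbn"
    model$head <- fit_softmax_head(up, y)
    if (epochs_finetune > 0) {
      model <- dbn_finetune(model, x, y, lr_finetune, epochs_finetune,
                            batch_size)
    }
    model
  })
}

split_batches <- function(ord, batch_size) {
  split(ord, ceiling(seq_along(ord) / batch_size))
}

# softmax head on frozen features: multinomial logit, first class = reference
fit_softmax_head <- function(feats, y) {
  df <- data.frame(feats)
  df$.y <- y
  fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, decay = 1e-4,
                        maxit = 200)
  cf <- coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
  W <- rbind(0, cf[, -1, drop = FALSE])   # C x d, reference row zero
  b <- c(0, cf[, 1])
  list(W = t(W), b = b)                   # store d x C
}

dbn_forward <- function(model, x) {
  acts <- list(x)
  up <- x
  for (p in model$layers) {
    up <- rbm_hidden_prob(up, p)
    acts[[length(acts) + 1]] <- up
  }
  logits <- sweep(up %*% model$head$W, 2, model$head$b, "+")
  list(acts = acts, top = up, prob = softmax_rows(logits))
}

dbn_finetune <- function(model, x, y, lr, epochs, batch_size) {
  Y <- class_indicator(y)
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nrow(x))
    for (batch in split_batches(ord, batch_size)) {
      xb <- x[batch, , drop = FALSE]
      fw <- dbn_forward(model, xb)
      B <- length(batch)
      dZ <- (fw$prob - Y[batch, , drop = FALSE]) / B
      dA <- tcrossprod(dZ, model$head$W)    # B x h_L, uses pre-update W
      model$head$W <- model$head$W - lr * crossprod(fw$top, dZ)
      model$head$b <- model$head$b - lr * colSums(dZ)
      for (l in rev(seq_along(model$layers))) {
        A <- fw$acts[[l + 1]]
        dpre <- dA * A * (1 - A)
        dA <- tcrossprod(dpre, model$layers[[l]]$w)
        model$layers[[l]]$w <- model$layers[[l]]$w -
          lr * crossprod(fw$acts[[l]], dpre)
        model$layers[[l]]$b <- model$layers[[l]]$b - lr * colSums(dpre)
      }
    }
    p <- dbn_forward(model, x)$prob
    hist[ep] <- -mean(log(pmax(p[cbind(seq_along(y), as.integer(y))], 1e-12)))
  }
  model$history <- data.frame(epoch = seq_len(epochs), loss = hist)
  model
}

#' Predict from a deep belief network
#'
#' @param object a fitted [dbn()] model.
#' @param newdata matrix (values in `[0, 1]`) or preprocessed
#'   [ckd_dataset()].
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @export
predict.dbn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "ckd_dataset")) newdata <- feature_matrix(newdata)
  newdata <- matrix(as.numeric(newdata), ncol = object$sizes[1])
  prob <- dbn_forward(object, newdata)$prob
  colnames(prob) <- object$classes
  if (type == "prob") prob
  else factor(object$classes[max.col(prob, ties.method = "first")],
              levels = object$classes)
}

#' DBN feature vector for ensemble fusion
#'
#' Top hidden-layer activation probabilities concatenated with the head's
#' class posteriors; length `h_L + C` per row.
#'
#' @param object a fitted [dbn()] model.
#' @param x one row or a matrix of rows.
#' @return numeric matrix (rows x (h_L + C)).
#' @export
dbn_features <- function(object, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- matrix(as.numeric(x), ncol = object$sizes[1])
  fw <- dbn_forward(object, x)
  cbind(fw$top, fw$prob)
}
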