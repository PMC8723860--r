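# Independent oracles used across the suite. Each one is deliberately a
# different computational route from the implementation it checks.

# --- exact RBM enumeration ---------------------------------------------------
# Enumerate all binary (v, h) states, form the Boltzmann joint from the energy,
# and read conditionals off by Bayes' rule.
all_binary_states <- function(n) {
  if (n == 0) return(matrix(numeric(0), nrow = 1, ncol = 0))
  as.matrix(expand.grid(rep(list(0:1), n)))
}

enumerate_rbm <- function(params) {
  nv <- nrow(params$w)
  nh <- ncol(params$w)
  V <- all_binary_states(nv)
  H <- all_binary_states(nh)
  E <- matrix(0, nrow(V), nrow(H))
  for (i in seq_len(nrow(V))) {
    for (j in seq_len(nrow(H))) {
      v <- V[i, ]; h <- H[j, ]
      E[i, j] <- -(sum(params$a * v) + sum(params$b * h) +
                     as.numeric(t(v) %*% params$w %*% h))
    }
  }
  un <- exp(-E)
  list(V = V, H = H, Z = sum(un), joint = un / sum(un))
}

# P(h_j = 1 | v) via Bayes on the enumerated joint
bayes_hidden_given_visible <- function(v, enum) {
  row <- which(apply(enum$V, 1, function(x) all(x == v)))
  pv <- enum$joint[row, ]
  vapply(seq_len(ncol(enum$H)), function(j) {
    sum(pv[enum$H[, j] == 1]) / sum(pv)
  }, numeric(1))
}

bayes_visible_given_hidden <- function(h, enum) {
  col <- which(apply(enum$H, 1, function(x) all(x == h)))
  ph <- enum$joint[, col]
  vapply(seq_len(ncol(enum$V)), function(i) {
    sum(ph[enum$V[, i] == 1]) / sum(ph)
  }, numeric(1))
}

# exact log-likelihood gradient of an RBM for a data batch
exact_rbm_gradient <- function(params, batch) {
  enum <- enumerate_rbm(params)
  ph_data <- plogis(sweep(batch %*% params$w, 2, params$b, "+"))
  pos_w <- crossprod(batch, ph_data) / nrow(batch)
  pos_a <- colMeans(batch)
  pos_b <- colMeans(ph_data)
  # model expectations by enumeration
  pv <- rowSums(enum$joint)
  ph <- colSums(enum$joint)
  neg_w <- matrix(0, nrow(params$w), ncol(params$w))
  for (i in seq_len(nrow(enum$V))) {
    for (j in seq_len(nrow(enum$H))) {
      neg_w <- neg_w + enum$joint[i, j] * tcrossprod(enum$V[i, ], enum$H[j, ])
    }
  }
  neg_a <- as.vector(pv %*% enum$V)
  neg_b <- as.vector(ph %*% enum$H)
  list(w = pos_w - neg_w, a = pos_a - neg_a, b = pos_b - neg_b)
}

# --- ridge-regression oracle for the linear-kernel KELM ----------------------
# Primal solve in feature space: A = (X'X + I/lambda)^{-1} X' T, predictions
# X_new A. Equal to the kernel (dual) route by the push-through identity.
ridge_oracle_predict <- function(X, y, X_new, lambda) {
  Tm <- ckdens:::class_indicator(as.factor(y))
  d <- ncol(X)
  X_new %*% solve(crossprod(X) + diag(d) / lambda, crossprod(X, Tm))
}

# --- rank-statistic AUC oracle ----------------------------------------------
# Mann-Whitney: P(score_pos > score_neg) + 0.5 P(tie).
rank_auc <- function(labels_pos, scores) {
  s_pos <- scores[labels_pos]
  s_neg <- scores[!labels_pos]
  cmp <- outer(s_pos, s_neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# --- independent ADASYN allocation -------------------------------------------
# Straight-line transcription of the sampling weights: for each minority row,
# count majority members among its k nearest rows (ties by index), normalize,
# and allocate G shares by largest remainder.
adasyn_alloc_oracle <- function(X, y, minority, k, beta) {
  counts <- table(y)
  majority <- setdiff(names(counts), minority)
  G <- round((max(counts) - min(counts)) * beta)
  min_idx <- which(y == minority)
  r <- numeric(length(min_idx))
  for (ii in seq_along(min_idx)) {
    i <- min_idx[ii]
    d <- sqrt(colSums((t(X) - X[i, ])^2))
    ord <- setdiff(order(d, seq_along(d)), i)[1:k]
    r[ii] <- sum(y[ord] == majority) / k
  }
  r_hat <- if (sum(r) == 0) rep(1 / length(r), length(r)) else r / sum(r)
  base <- floor(G * r_hat)
  rem <- G - sum(base)
  if (rem > 0) {
    frac <- G * r_hat - base
    base[order(-frac, seq_along(frac))[seq_len(rem)]] <-
      base[order(-frac, seq_along(frac))[seq_len(rem)]] + 1
  }
  list(G = G, g = as.integer(base), r_hat = r_hat)
}

# --- shared fixtures ---------------------------------------------------------
# small fully-observed preprocessed dataset
make_processed_fixture <- function(n_pos = 60, n_neg = 40, sep = 2.5,
                                   seed = 1) {
  ds <- ckd_synthesize(n_positive = n_pos, n_negative = n_neg,
                       class_separation = sep, missing_rate = 0, seed = seed)
  ckd_preprocess(ds)$data
}

# fast model settings used wherever a test needs a trained ensemble
fast_dbn_args <- list(hidden = c(16, 8), epochs_pretrain = 3,
                      epochs_finetune = 15)
fast_cnn_args <- list(n_kernels = 4, gru_input = 8, gru_hidden = 12,
                      gru_output = 4, epochs = 25)
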