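#' Butterfly-optimization primitives
#'
#' `fragrance()` computes the perceived fragrance `f = c * I^a` of a
#' butterfly with stimulus intensity `I >= 0`, sensor modality `c > 0` and
#' power exponent `a`. `quasi_opposite()` draws, per dimension, a uniform
#' value between the search-space midpoint `(min + max) / 2` and the mirror
#' point `min + max - x` (endpoints ordered before sampling); a point at the
#' midpoint is its own quasi-opposite. `boa_global_move()` and
#' `boa_local_move()` are the two BOA move rules
#' `x + (alpha^2 * g_star - x) * f` and `x + (alpha^2 * x_j - x_k) * f`
#' with `alpha ~ U(0, 1)` drawn per move; when bounds are supplied the
#' result is clipped into them.
#'
#' @param intensity stimulus intensity `I` (>= 0; vectorized).
#' @param c sensor modality (> 0).
#' @param a power exponent.
#' @return numeric vector.
#' @examples
#' fragrance(4, c = 1, a = 0.5)       # 2
#' range(replicate(50, quasi_opposite(2, 0, 10)))  # inside [5, 8]
#' @export
fragrance <- function(intensity, c = 0.01, a = 0.1) {
  if (any(intensity < 0)) stop("stimulus intensity must be non-negative")
  stopifnot(c > 0)
  c * intensity^a
}

#' @rdname fragrance
#' @param x position vector (within bounds).
#' @param lower,upper per-dimension bounds.
#' @param seed RNG seed.
#' @export
quasi_opposite <- function(x, lower, upper, seed = NULL) {
  stopifnot(length(lower) %in% c(1, length(x)),
            length(upper) %in% c(1, length(x)))
  lower <- rep_len(lower, length(x))
  upper <- rep_len(upper, length(x))
  if (any(x < lower | x > upper)) stop("position outside the search bounds")
  mid <- (lower + upper) / 2
  mirror <- lower + upper - x
  with_seed_or_not(seed, {
    runif(length(x), pmin(mid, mirror), pmax(mid, mirror))
  })
}

#' @rdname fragrance
#' @param g_star current global best position.
#' @param f fragrance of the moving butterfly.
#' @param alpha the uniform draw; defaults to a fresh `runif(1)`.
#' @export
boa_global_move <- function(x, g_star, f, alpha = NULL,
                            lower = NULL, upper = NULL) {
  if (is.null(alpha)) alpha <- runif(1)
  clip_bounds(x + (alpha^2 * g_star - x) * f, lower, upper)
}

#' @rdname fragrance
#' @param x_j,x_k two distinct population members.
#' @export
boa_local_move <- function(x, x_j, x_k, f, alpha = NULL,
                           lower = NULL, upper = NULL) {
  if (is.null(alpha)) alpha <- runif(1)
  clip_bounds(x + (alpha^2 * x_j - x_k) * f, lower, upper)
}

clip_bounds <- function(x, lower, upper) {
  if (!is.null(lower)) x <- pmax(x, lower)
  if (!is.null(upper)) x <- pmin(x, upper)
  x
}

#' Define a box-constrained search space
#'
#' @param name per-dimension names.
#' @param min,max per-dimension bounds (`min <= max`; equal bounds pin the
#'   dimension).
#' @param type `"continuous"`, `"integer"` (rounded after clipping) or
#'   `"log"` (searched on the log10 scale).
#' @return a `data.frame` describing the space.
#' @examples
#' search_space(c("h1", "lr"), min = c(4, 1e-3), max = c(64, 0.3),
#'              type = c("integer", "log"))
#' @export
search_space <- function(name, min, max, type = "continuous") {
  stopifnot(length(min) == length(name), length(max) == length(name),
            all(min <= max))
  type <- rep_len(type, length(name))
  stopifnot(all(type %in% c("continuous", "integer", "log")))
  if (any(type == "log" & min <= 0)) stop("log-scaled dimensions need min > 0")
  data.frame(name = name, min = min, max = max, type = type,
             stringsAsFactors = FALSE)
}

space_encode_bounds <- function(space) {
  lo <- ifelse(space$type == "log", log10(space$min), space$min)
  hi <- ifelse(space$type == "log", log10(space$max), space$max)
  list(lo = lo, hi = hi)
}

space_repair <- function(x, space, lo, hi) {
  x <- pmin(pmax(x, lo), hi)
  ix <- space$type == "integer"
  x[ix] <- round(x[ix])
  x
}

space_decode <- function(x, space) {
  out <- ifelse(space$type == "log", 10^x, x)
  out[space$type == "integer"] <- round(out[space$type == "integer"])
  stats::setNames(out, space$name)
}

#' Quasi-oppositional butterfly optimization
#'
#' Minimizes `fn` over a box-constrained space. The population is
#' initialized uniformly and augmented with the quasi-opposites of every
#' member; the best `pop_size` of the union survive. Each iteration, each
#' butterfly makes a global move towards the elitist best `g_star` with
#' probability `p`, otherwise a local move using two population members
#' drawn without replacement; moves are scaled by the fragrance
#' `c_t * I^a`, where the stimulus `I` is the butterfly's normalized
#' fitness rank in `(0, 1]` (best = 1) and the sensor modality follows the
#' reference schedule `c_t <- c_t + 0.025 / (c_t * max_iter)`. Moves are
#' accepted greedily (only if they improve) and the global best is elitist,
#' so the best-so-far curve is non-increasing.
#'
#' @param fn objective to minimize; receives a named numeric vector on the
#'   original (decoded) scale and must return a finite scalar.
#' @param space a [search_space()].
#' @param pop_size population size (>= 2).
#' @param max_iter iteration budget.
#' @param c initial sensor modality; `a` power exponent; `p` global-search
#'   switch probability.
#' @param a,p see above.
#' @param quasi_opposition `"init_only"` (default), `"jumping"` (also
#'   re-oppose the population with probability `jump_rate` per iteration)
#'   or `"none"`.
#' @param jump_rate jumping rate for `quasi_opposition = "jumping"`.
#' @param seed RNG seed.
#' @return list with `par` (best decoded position), `value` (its fitness),
#'   `history` (best-so-far per iteration) and `evaluations`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' sp <- search_space(c("x1", "x2"), min = c(-5, -5), max = c(5, 5))
#' qoboa(sphere, sp, max_iter = 20, seed = 1)$value
#' @export
qoboa <- function(fn, space, pop_size = 20, max_iter = 50,
                  c = 0.01, a = 0.1, p = 0.8,
                  quasi_opposition = c("init_only", "jumping", "none"),
                  jump_rate = 0.1, seed = NULL) {
  stopifnot(pop_size >= 2, max_iter >= 1, c > 0, a > 0, a <= 1,
            p >= 0, p <= 1)
  quasi_opposition <- match.arg(quasi_opposition)
  b <- space_encode_bounds(space)
  D <- nrow(space)
  evals <- 0L
  eval_fn <- function(x) {
    evals <<- evals + 1L
    val <- fn(space_decode(x, space))
    if (!is.finite(val)) stop("objective returned a non-finite value")
    val
  }
  repair_rows <- function(M) {
    for (i in seq_len(nrow(M))) {
      M[i, ] <- space_repair(M[i, ], space, b$lo, b$hi)
    }
    M
  }
  quasi_rows <- function(M) {
    for (i in seq_len(nrow(M))) {
      M[i, ] <- space_repair(quasi_opposite(M[i, ], b$lo, b$hi),
                             space, b$lo, b$hi)
    }
    M
  }
  with_seed_or_not(seed, {
    pop <- matrix(runif(pop_size * D), pop_size, D)
    pop <- repair_rows(sweep(sweep(pop, 2, b$hi - b$lo, "*"), 2, b$lo, "+"))
    cand <- if (quasi_opposition != "none") rbind(pop, quasi_rows(pop)) else pop
    fit_all <- apply(cand, 1, eval_fn)
    keep <- order(fit_all, seq_along(fit_all))[seq_len(pop_size)]
    pop <- cand[keep, , drop = FALSE]
    fitness <- fit_all[keep]
    gbest_i <- which.min(fitness)
    g_star <- pop[gbest_i, ]
    g_fit <- fitness[gbest_i]
    history <- numeric(max_iter)
    c_t <- c
    for (t in seq_len(max_iter)) {
      rk <- rank(fitness, ties.method = "first")
      I <- (pop_size - rk + 1) / pop_size      # best = 1
      f <- fragrance(I, c = c_t, a = a)
      for (i in seq_len(pop_size)) {
        x <- pop[i, ]
        cand_x <- if (runif(1) < p) {
          boa_global_move(x, g_star, f[i])
        } else {
          jk <- sample.int(pop_size, 2L)
          boa_local_move(x, pop[jk[1], ], pop[jk[2], ], f[i])
        }
        cand_x <- space_repair(cand_x, space, b$lo, b$hi)
        val <- eval_fn(cand_x)
        if (val < fitness[i]) {
          pop[i, ] <- cand_x
          fitness[i] <- val
          if (val < g_fit) {
            g_fit <- val
            g_star <- cand_x
          }
        }
      }
      if (quasi_opposition == "jumping" && runif(1) < jump_rate) {
        qo <- quasi_rows(pop)
        qfit <- apply(qo, 1, eval_fn)
        un <- rbind(pop, qo)
        uf <- c(fitness, qfit)
        keep <- order(uf, seq_along(uf))[seq_len(pop_size)]
        pop <- un[keep, , drop = FALSE]
        fitness <- uf[keep]
        if (min(fitness) < g_fit) {
          g_fit <- min(fitness)
          g_star <- pop[which.min(fitness), ]
        }
      }
      c_t <- c_t + 0.025 / (c_t * max_iter)    # reference modality schedule
      history[t] <- g_fit
    }
    list(par = space_decode(g_star, space), value = g_fit,
         history = history, evaluations = evals)
  })
}

#' Tune classifier hyperparameters with QOBOA
#'
#' Minimizes `1 - validation accuracy` under a stratified holdout of the
#' training data. The inner seed is fixed per candidate so that two
#' evaluations of the same position return the same fitness. If every
#' dimension of the space is pinned (`min == max`) the single point is
#' evaluated once and returned.
#'
#' Default search spaces: for `"dbn"`, hidden sizes `h1` in `[8, 64]` and
#' `h2` in `[4, 32]`, learning rates in `[1e-3, 0.3]` (log scale) and the
#' fine-tuning epoch count in `[5, 40]`; for `"cnn_gru"`, kernel count in
#' `[2, 12]`, GRU hidden size in `[4, 32]`, learning rate in `[1e-3, 0.3]`
#' (log) and epochs in `[5, 30]`.
#'
#' @param family `"dbn"` or `"cnn_gru"`.
#' @param ds preprocessed training [ckd_dataset()].
#' @param space a [search_space()]; `NULL` uses the family default.
#' @param pop_size,max_iter QOBOA budget (small defaults: each evaluation
#'   trains a model).
#' @param eval_fraction held-out validation fraction.
#' @param inner_seed seed for the inner split and every candidate training.
#' @param seed seed for the optimizer itself.
#' @param ... passed on to [qoboa()].
#' @return list with `best` (named hyperparameters), `value`
#'   (1 - validation accuracy) and the optimizer `history`.
#' @export
tune_qoboa <- function(family = c("dbn", "cnn_gru"), ds, space = NULL,
                       pop_size = 6, max_iter = 5, eval_fraction = 0.25,
                       inner_seed = 1, seed = NULL, ...) {
  family <- match.arg(family)
  if (is.null(space)) space <- default_space(family)
  split <- stratified_split(ds$y, "holdout", fraction = eval_fraction,
                            seed = inner_seed)
  X <- feature_matrix(ds)
  xtr <- X[split$train, , drop = FALSE]
  ytr <- ds$y[split$train]
  xva <- X[split$test, , drop = FALSE]
  yva <- ds$y[split$test]
  objective <- function(par) {
    fit <- train_family(family, xtr, ytr, par, inner_seed)
    1 - mean(predict(fit, xva) == yva)
  }
  if (all(space$min == space$max)) {
    par <- space_decode(space_encode_bounds(space)$lo, space)
    return(list(best = par, value = objective(par), history = numeric(0)))
  }
  opt <- qoboa(objective, space, pop_size = pop_size, max_iter = max_iter,
               seed = seed, ...)
  list(best = opt$par, value = opt$value, history = opt$history)
}

default_space <- function(family) {
  if (family == "dbn") {
    search_space(c("h1", "h2", "lr_pretrain", "lr_finetune", "epochs"),
                 min = c(8, 4, 1e-3, 1e-3, 5),
                 max = c(64, 32, 0.3, 0.3, 40),
                 type = c("integer", "integer", "log", "log", "integer"))
  } else {
    search_space(c("n_kernels", "gru_hidden", "lr", "epochs"),
                 min = c(2, 4, 1e-3, 5),
                 max = c(12, 32, 0.3, 30),
                 type = c("integer", "integer", "log", "integer"))
  }
}

train_family <- function(family, x, y, par, seed) {
  if (family == "dbn") {
    dbn(x, y, hidden = c(par[["h1"]], par[["h2"]]),
        lr_pretrain = par[["lr_pretrain"]], lr_finetune = par[["lr_finetune"]],
        epochs_pretrain = 5, epochs_finetune = par[["epochs"]], seed = seed)
  } else {
    cnn_gru(x, y, n_kernels = par[["n_kernels"]],
            gru_hidden = par[["gru_hidden"]], gru_input = 8, gru_output = 4,
            lr = par[["lr"]], epochs = par[["epochs"]], seed = seed)
  }
}
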