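#' ADASYN minority oversampling
#'
#' Adaptive synthetic sampling for imbalanced two-class data: synthetic
#' minority points are allocated preferentially to minority samples whose
#' k-nearest neighbourhoods (Euclidean distance over all rows) contain many
#' majority samples, i.e. to the hard, class-boundary region. Each synthetic
#' point is `x_i + lambda * (x_z - x_i)` with `lambda ~ U(0, 1)` and `x_z` a
#' uniformly chosen member of `x_i`'s k nearest *minority* neighbours, so
#' synthetics are coordinate-wise convex combinations of minority pairs.
#' Majority rows pass through unchanged and original rows are never removed.
#'
#' The total synthetic count is `G = round((m_l - m_s) * beta)` for majority
#' and minority counts `m_l`, `m_s`; per-point shares `g_i` follow the
#' normalized neighbourhood weights via largest-remainder rounding (so
#' `sum(g_i) == G` exactly). Neighbour-distance ties break by row index. If
#' no minority point has any majority neighbour the weights fall back to
#' uniform, with a message.
#'
#' @param ds a preprocessed [ckd_dataset()] (numeric, no missing values), or
#'   a numeric matrix together with `y`.
#' @param y labels when `ds` is a matrix; ignored otherwise.
#' @param k_neighbors neighbour count for the density estimate (default 5).
#' @param beta desired balance level in `[0, 1]`; 1 (default) fully
#'   rebalances.
#' @param seed RNG seed.
#' @return the input dataset with synthetic minority rows appended; the
#'   `"adasyn"` attribute records `G`, the per-point allocation `g`, the
#'   weights `r_hat` and the minority label.
#' @examples
#' ds <- ckd_preprocess(ckd_synthesize(n_positive = 50, n_negative = 30,
#'                                     missing_rate = 0, seed = 1))$data
#' bal <- adasyn(ds, seed = 2)
#' table(bal$y)
#' @export
adasyn <- function(ds, y = NULL, k_neighbors = 5, beta = 1, seed = NULL) {
  stopifnot(k_neighbors >= 1, beta >= 0, beta <= 1)
  if (is.matrix(ds)) {
    X <- ds
    y <- as.factor(y)
    ds_out <- NULL
  } else {
    X <- feature_matrix(ds)
    y <- ds$y
    ds_out <- ds
  }
  if (anyNA(X)) stop("ADASYN requires preprocessed data with no missing values")
  counts <- table(y)
  present <- names(counts)[counts > 0]
  if (length(present) < 2L) stop("ADASYN requires both classes present")
  minority <- present[which.min(counts[present])]
  majority <- present[which.max(counts[present])]
  m_s <- as.integer(counts[minority])
  m_l <- as.integer(counts[majority])
  G <- round((m_l - m_s) * beta)
  info <- list(G = G, g = integer(0), r_hat = numeric(0), minority = minority)
  if (G == 0L) {
    message("classes already balanced at beta = ", beta, "; nothing to do")
    return(add_adasyn_attr(ds_out, X, y, NULL, info))
  }
  min_idx <- which(y == minority)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  k_all <- min(k_neighbors, n - 1L)
  with_seed_or_not(seed, {
    delta <- vapply(min_idx, function(i) {
      nb <- order_ties_by_index(D[i, ], exclude = i)[seq_len(k_all)]
      sum(y[nb] == majority)
    }, numeric(1))
    r <- delta / k_all
    if (sum(r) == 0) {
      message("no minority point has majority neighbours; using uniform weights")
      r_hat <- rep(1 / m_s, m_s)
    } else {
      r_hat <- r / sum(r)
    }
    g <- largest_remainder(G, r_hat)
    # donor pools: k nearest minority neighbours of each minority point
    k_min <- min(k_neighbors, m_s - 1L)
    synth <- matrix(NA_real_, nrow = G, ncol = ncol(X))
    row <- 0L
    for (ii in seq_along(min_idx)) {
      if (g[ii] == 0L) next
      i <- min_idx[ii]
      pool <- if (k_min >= 1L) {
        others <- setdiff(min_idx, i)
        others[order_ties_by_index(D[i, others])][seq_len(k_min)]
      } else i   # singleton minority: duplicate in place
      for (s in seq_len(g[ii])) {
        z <- pool[sample.int(length(pool), 1L)]
        lam <- runif(1)
        row <- row + 1L
        synth[row, ] <- X[i, ] + lam * (X[z, ] - X[i, ])
      }
    }
    info$g <- stats::setNames(g, min_idx)
    info$r_hat <- stats::setNames(r_hat, min_idx)
    colnames(synth) <- colnames(X)
    add_adasyn_attr(ds_out, X, y, synth, info)
  })
}

add_adasyn_attr <- function(ds_out, X, y, synth, info) {
  if (!is.null(synth)) {
    X <- rbind(X, synth)
    y <- factor(c(as.character(y), rep(info$minority, nrow(synth))),
                levels = levels(y))
  }
  out <- if (is.null(ds_out)) {
    list(X = X, y = y)
  } else {
    ds_out$X <- X
    ds_out$y <- y
    ds_out$provenance <- paste0(ds_out$provenance, " |adasyn")
    ds_out
  }
  attr(out, "adasyn") <- info
  out
}

# order values ascending, ties broken by (row) index, optionally dropping one
order_ties_by_index <- function(d, exclude = NULL) {
  idx <- seq_along(d)
  ord <- idx[order(d, idx)]
  if (!is.null(exclude)) ord <- ord[ord != exclude]
  ord
}

# integer allocation of `total` proportional to `w` (sums exactly to total)
largest_remainder <- function(total, w) {
  raw <- total * w
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- raw - base
    top <- order(-frac, seq_along(w))[seq_len(rem)]
    base[top] <- base[top] + 1L
  }
  as.integer(base)
}
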