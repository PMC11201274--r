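# Symmetric-normalized graph convolution stack shared by both models:
#   H^{l+1} = ReLU( Abar H^l W^l + b^l ),  Abar = D~^{-1/2} (A+I) D~^{-1/2}
# Six weight matrices: d_in->256, four 256->256, 256->16.  Written in plain
# matrix code with hand-derived gradients; sparse propagation via Matrix.

#' Symmetric-normalized adjacency operator with self-loops
#'
#' Computes `Abar = D~^{-1/2} (A + I) D~^{-1/2}` where `D~` is the degree
#' matrix of `A + I`.  Self-loops keep isolated nodes well-defined and stop
#' zero-degree rows from annihilating their features.
#'
#' @param edges 2-column matrix of 1-based undirected index pairs.
#' @param n Number of nodes.
#' @return Object of class `graph_operator` wrapping a sparse symmetric
#'   matrix `Abar` (`$A`) and `n`.
#' @export
normalized_adjacency <- function(edges, n) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges)) {
    sg_assert(all(edges >= 1L & edges <= n), "edge index out of range")
    sg_assert(all(edges[, 1] != edges[, 2]), "self-pairs are not allowed")
  }
  i <- c(edges[, 1], edges[, 2], seq_len(n))
  j <- c(edges[, 2], edges[, 1], seq_len(n))
  A1 <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  dinv <- 1 / sqrt(Matrix::rowSums(A1))
  Abar <- Matrix::Diagonal(x = dinv) %*% A1 %*% Matrix::Diagonal(x = dinv)
  structure(list(A = Abar, n = n), class = "graph_operator")
}

#' Initialize a GCN weight stack
#'
#' Glorot-uniform weights, zero biases; six layers
#' (`d_in`->`hidden`, 4x `hidden`->`hidden`, `hidden`->`d_out`).
#'
#' @param d_in Input feature dimension.
#' @param hidden Hidden width (default 256).
#' @param d_out Output embedding width (default 16).
#' @param bias Use per-layer bias (default `TRUE`).
#' @param seed Integer seed for the initialization.
#' @return Object of class `gcn_stack`: lists `W` and `b`.
#' @export
gcn_init <- function(d_in, hidden = 256L, d_out = 16L, bias = TRUE,
                     seed = 1L) {
  dims <- c(d_in, rep(hidden, 5L), d_out)
  with_rng(seed, {
    W <- lapply(seq_len(6L), function(l)
      glorot(dims[l], dims[l + 1L]))
    b <- lapply(seq_len(6L), function(l)
      if (bias) numeric(dims[l + 1L]) else NULL)
    structure(list(W = W, b = b, dims = dims, bias = bias),
              class = "gcn_stack")
  })
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Forward pass through the GCN stack
#'
#' @param stack A `gcn_stack`.
#' @param X Node feature matrix (`n x d_in`).
#' @param op A `graph_operator` from [normalized_adjacency()].
#' @param keep_cache Return intermediate activations for backprop.
#' @return `H6` (`n x d_out`), or, with `keep_cache`, a list `H6`, `cache`.
#' @export
gcn_forward <- function(stack, X, op, keep_cache = FALSE) {
  X <- as.matrix(X)
  sg_assert(nrow(X) == op$n, "X row count must equal node count")
  sg_assert(ncol(X) == stack$dims[1], "input width mismatch with W0")
  H <- X
  cache <- if (keep_cache) list(AH = vector("list", 6L),
                                Z = vector("list", 6L))
  for (l in seq_len(6L)) {
    AH <- as.matrix(op$A %*% H)
    Z <- AH %*% stack$W[[l]]
    if (!is.null(stack$b[[l]])) Z <- sweep(Z, 2L, stack$b[[l]], "+")
    if (keep_cache) { cache$AH[[l]] <- AH; cache$Z[[l]] <- Z }
    H <- pmax(Z, 0)
  }
  if (keep_cache) list(H6 = H, cache = cache) else H
}

# Backward pass: given dL/dH6, return gradients for every W/b and dL/dX.
gcn_backward <- function(stack, op, cache, dH6) {
  dW <- vector("list", 6L); db <- vector("list", 6L)
  dH <- dH6
  for (l in 6L:1L) {
    dZ <- dH * (cache$Z[[l]] > 0)
    dW[[l]] <- crossprod(cache$AH[[l]], dZ)
    if (!is.null(stack$b[[l]])) db[[l]] <- colSums(dZ)
    # Abar is symmetric: dH^{l} = Abar (dZ W^T)
    dH <- as.matrix(op$A %*% (dZ %*% t(stack$W[[l]])))
  }
  list(dW = dW, db = db, dX = dH)
}

#' Count trainable parameters of a GCN stack
#' @param stack A `gcn_stack`.
#' @return Integer parameter count.
#' @export
gcn_n_params <- function(stack) {
  sum(vapply(stack$W, length, 0L)) +
    sum(vapply(stack$b, function(b) length(b %||% numeric(0)), 0L))
}

## ---- Adam optimizer on arbitrary lists of arrays -------------------------

adam_init <- function(params) {
  zero <- function(p) {
    if (is.null(p)) NULL
    else if (is.list(p)) lapply(p, zero)
    else p * 0
  }
  z <- zero(params)
  list(m = z, v = z, t = 0L)
}

# One Adam step with decoupled-from-nothing classic L2 weight decay added to
# the gradient (PyTorch Adam semantics).
adam_step <- function(params, grads, state, lr = 1e-3, weight_decay = 5e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.null(p) || is.null(g)) return(list(p = p, m = m, v = v))
    g <- g + weight_decay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.null(p)) return(list(p = NULL, m = NULL, v = NULL))
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else upd(p, g, m, v)
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}
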