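# LSTM sequence head over the node embeddings: single layer, input 16,
# hidden 256, gate order (i, f, g, o), followed by a linear map
# 256 -> 2 applied at every step so each node gets its own logit pair.
# The linear map alone has 256*2 + 2 = 514 trainable scalars.

#' Initialize an LSTM classification head
#'
#' @param d_in Input width (GCN embedding size, default 16).
#' @param hidden Hidden state width (default 256).
#' @param d_out Number of classes (default 2).
#' @param seed Integer seed.
#' @return Object of class `lstm_head`: `Wx` (`4*hidden x d_in`), `Wh`
#'   (`4*hidden x hidden`), `b` (`4*hidden`, forget-gate slice initialized
#'   to 1), `W_out` (`d_out x hidden`), `b_out`.
#' @export
lstm_init <- function(d_in = 16L, hidden = 256L, d_out = 2L, seed = 1L) {
  with_rng(seed, {
    h4 <- 4L * hidden
    b <- numeric(h4)
    b[(hidden + 1L):(2L * hidden)] <- 1          # forget-gate bias
    structure(list(
      Wx = t(glorot(d_in, h4)), Wh = t(glorot(hidden, h4)), b = b,
      W_out = t(glorot(hidden, d_out)), b_out = numeric(d_out),
      d_in = d_in, hidden = hidden, d_out = d_out
    ), class = "lstm_head")
  })
}

#' Trainable parameter count of an LSTM head
#'
#' @param head An `lstm_head`.
#' @param part `"all"`, `"lstm"` (gates only) or `"fc"` (output linear map
#'   only; 514 for hidden 256 and 2 classes).
#' @return Integer count.
#' @export
lstm_n_params <- function(head, part = c("all", "lstm", "fc")) {
  part <- match.arg(part)
  fc <- length(head$W_out) + length(head$b_out)
  gates <- length(head$Wx) + length(head$Wh) + length(head$b)
  switch(part, all = gates + fc, lstm = gates, fc = fc)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Forward pass of the LSTM head over a node-embedding sequence
#'
#' Runs the standard LSTM recurrence over the rows of `H6` (nodes ordered
#' by window start time) and emits `logits_t = W_out h_t + b_out` at every
#' step.  With `final_state_only = TRUE` only the last step's logits are
#' returned (the sequence-level reading of the model).
#'
#' @param head An `lstm_head`.
#' @param H6 Matrix `n x d_in` of node embeddings in sequence order.
#' @param keep_cache Keep intermediates for backprop.
#' @param final_state_only Return only the final step's logits.
#' @return Logits matrix (`n x d_out`, or `1 x d_out`), or a list with
#'   `logits` and `cache`.
#' @export
lstm_head_forward <- function(head, H6, keep_cache = FALSE,
                              final_state_only = FALSE) {
  H6 <- as.matrix(H6)
  sg_assert(ncol(H6) == head$d_in, "input width mismatch with the LSTM head")
  n <- nrow(H6); hd <- head$hidden
  i_idx <- 1:hd; f_idx <- (hd + 1L):(2L * hd)
  g_idx <- (2L * hd + 1L):(3L * hd); o_idx <- (3L * hd + 1L):(4L * hd)

  Xp <- H6 %*% t(head$Wx)                       # n x 4h, input projections
  G <- matrix(0, n, 4L * hd)                    # post-activation gates
  Cs <- matrix(0, n, hd); Hs <- matrix(0, n, hd)
  h <- numeric(hd); cc <- numeric(hd)
  for (t in seq_len(n)) {
    a <- Xp[t, ] + as.vector(head$Wh %*% h) + head$b
    gi <- sigmoid(a[i_idx]); gf <- sigmoid(a[f_idx])
    gg <- tanh(a[g_idx]);    go <- sigmoid(a[o_idx])
    cc <- gf * cc + gi * gg
    h <- go * tanh(cc)
    G[t, ] <- c(gi, gf, gg, go); Cs[t, ] <- cc; Hs[t, ] <- h
  }
  logits <- sweep(Hs %*% t(head$W_out), 2L, head$b_out, "+")
  if (final_state_only) logits <- logits[n, , drop = FALSE]
  if (!keep_cache) return(logits)
  list(logits = logits,
       cache = list(G = G, Cs = Cs, Hs = Hs, X = H6,
                    idx = list(i = i_idx, f = f_idx, g = g_idx, o = o_idx)))
}

# BPTT through the LSTM head.  dlogits: n x d_out.  Returns gradients for
# all head parameters and dL/dH6.
lstm_backward <- function(head, cache, dlogits) {
  n <- nrow(cache$X); hd <- head$hidden
  ii <- cache$idx$i; fi <- cache$idx$f; gi_ <- cache$idx$g; oi <- cache$idx$o
  dW_out <- crossprod(dlogits, cache$Hs)        # d_out x hidden
  db_out <- colSums(dlogits)
  dH_direct <- dlogits %*% head$W_out           # n x hidden

  dA <- matrix(0, n, 4L * hd)                   # pre-activation grads
  dh_next <- numeric(hd); dc_next <- numeric(hd)
  for (t in n:1L) {
    gI <- cache$G[t, ii]; gF <- cache$G[t, fi]
    gG <- cache$G[t, gi_]; gO <- cache$G[t, oi]
    ct <- cache$Cs[t, ]; tc <- tanh(ct)
    c_prev <- if (t > 1L) cache$Cs[t - 1L, ] else numeric(hd)
    dh <- dH_direct[t, ] + dh_next
    dc <- dc_next + dh * gO * (1 - tc^2)
    da <- c(dc * gG * gI * (1 - gI),            # input gate
            dc * c_prev * gF * (1 - gF),        # forget gate
            dc * gI * (1 - gG^2),               # candidate
            dh * tc * gO * (1 - gO))            # output gate
    dA[t, ] <- da
    dh_next <- as.vector(crossprod(head$Wh, da))
    dc_next <- dc * gF
  }
  H_prev <- rbind(numeric(hd), cache$Hs[-n, , drop = FALSE])
  list(dWx = crossprod(dA, cache$X), dWh = crossprod(dA, H_prev),
       db = colSums(dA), dW_out = dW_out, db_out = db_out,
       dX = dA %*% head$Wx)
}
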