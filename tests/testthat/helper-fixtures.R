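# Shared fixtures, all generated in code at test time.

# Short synthetic recording for plumbing tests.
tiny_recording <- function(duration_s = 60, intervals = rbind(c(20, 40)),
                           seed = 7, n_channels = 4) {
  simulate_recording(sim_config(duration_s, n_channels = n_channels,
                                seizure_intervals = intervals, seed = seed))
}

# Two well-separated Gaussian clusters packaged as a feature_matrix, so the
# trainers can be exercised without the EEG feature pipeline.
toy_feature_matrix <- function(n = 60, d = 6, sep = 3, imbalance = 0.3,
                               seed = 42) {
  withr::with_seed(seed, {
    n1 <- round(n * imbalance)
    n0 <- n - n1
    X <- rbind(matrix(rnorm(n0 * d), n0),
               matrix(rnorm(n1 * d, mean = sep), n1))
    y <- c(rep(0L, n0), rep(1L, n1))
    ord <- sample(n)                  # interleave classes along "time"
    structure(list(X = X[ord, ], y = y[ord],
                   feature_names = paste0("f", seq_len(d)),
                   start_times = (seq_len(n) - 1) * 21,
                   fs = 256, window_s = 30, overlap_frac = 0.3,
                   scaler_state = NULL, spec = feature_spec()),
              class = "feature_matrix")
  })
}

# Independent periodogram band power: direct FFT, no package code.
fft_band_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= f_lo & f <= f_hi & f <= fs / 2
  sum(P[keep])
}

# Independent exhaustive pairwise-concordance AUC oracle.
pairwise_auc <- function(y, score) {
  pos <- score[y == 1]; neg <- score[y == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Independent O(n^2) edge enumeration for the distance-threshold graph.
brute_force_edges <- function(X, threshold) {
  n <- nrow(X)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((X[i, ] - X[j, ])^2)) < threshold)
        out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (length(out)) do.call(rbind, out) else matrix(integer(0), ncol = 2)
}

edge_key <- function(edges) {
  if (!nrow(edges)) return(character(0))
  sort(paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2])))
}

# Dense-matrix normalized adjacency, written independently of the package.
dense_norm_adj <- function(edges, n) {
  A <- matrix(0, n, n)
  if (nrow(edges)) {
    A[edges] <- 1
    A[edges[, c(2, 1), drop = FALSE]] <- 1
  }
  A <- A + diag(n)
  d <- rowSums(A)
  diag(1 / sqrt(d)) %*% A %*% diag(1 / sqrt(d))
}
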