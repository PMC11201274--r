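# Per-channel feature families (statistical, Daubechies-wavelet, spectral),
# cross-channel aggregation into one row per window, and min-max scaling.

#' Feature extraction specification
#'
#' @param profile `"compact19"` (default): 15 statistical features +
#'   approximation-coefficient mean + pooled detail standard deviation +
#'   total spectral power + spectral entropy = 19 per-channel features,
#'   which after cross-channel mean/variance aggregation gives 38 columns.
#'   `"extended"`: adds per-level detail SDs, per-subband energies and the
#'   five clinical band powers.
#' @param wavelet Daubechies wavelet name (default `"db8"`).
#' @param levels DWT decomposition levels (default 5; at 256 Hz the detail
#'   subbands then align with the clinical bands and the approximation
#'   covers 0-4 Hz).
#' @param entropy_bins Number of equal-width amplitude histogram bins for
#'   Shannon entropy (default 100).
#' @param band_edges Named list of `c(lo, hi)` band edges in Hz.
#' @param nperseg Welch segment length in samples (default 256).
#' @return Object of class `feature_spec`.
#' @export
feature_spec <- function(profile = c("compact19", "extended"),
                         wavelet = "db8", levels = 5L, entropy_bins = 100L,
                         band_edges = list(delta = c(0.5, 4), theta = c(4, 8),
                                           alpha = c(8, 13), beta = c(13, 30),
                                           gamma = c(30, 100)),
                         nperseg = 256L) {
  profile <- match.arg(profile)
  sg_assert(levels >= 1L, "levels must be >= 1")
  sg_assert(all(vapply(band_edges, function(b) b[1] < b[2], TRUE)),
            "band edges must be strictly increasing")
  structure(list(profile = profile, wavelet = wavelet, levels = as.integer(levels),
                 entropy_bins = as.integer(entropy_bins),
                 band_edges = band_edges, nperseg = as.integer(nperseg)),
            class = "feature_spec")
}

STATISTICAL_FEATURE_NAMES <- c(
  "mean", "variance", "median", "skewness", "kurtosis", "min", "max",
  "cv", "iqr", "energy", "avg_power", "line_length",
  "amplitude_integrated", "nonlinear_energy", "shannon_entropy")

#' The 15 statistical time-domain features of a single-channel window
#'
#' Order: mean, population variance, median, skewness (standardized third
#' central moment), excess kurtosis, min, max, coefficient of variation
#' (population SD / mean; 0 with a warning when the mean is 0), interquartile
#' range, energy (sum of squares), average power (energy/N), line length
#' (sum of absolute first differences), amplitude-integrated (sum of absolute
#' values), non-linear (Teager) energy (mean of `x_i^2 - x_{i-1} x_{i+1}`),
#' and Shannon entropy of a fixed-bin amplitude histogram over the window's
#' own range (scale-invariant).
#'
#' @param x Numeric window of length >= 3.
#' @param entropy_bins Histogram bin count for Shannon entropy.
#' @return Named numeric vector of length 15.
#' @export
statistical_features <- function(x, entropy_bins = 100L) {
  sg_assert(length(x) >= 3L, "window must have at least 3 samples")
  sg_assert(all(is.finite(x)), "window must be finite")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)                      # population variance
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 - 3 else 0
  cv <- if (mu == 0) {
    warning("coefficient of variation undefined for zero-mean window; reporting 0")
    0
  } else sqrt(m2) / mu
  energy <- sum(x^2)
  teager <- if (n >= 3L) mean(x[2:(n - 1L)]^2 - x[1:(n - 2L)] * x[3:n]) else 0
  c(mean = mu, variance = m2, median = stats::median(x),
    skewness = skew, kurtosis = kurt, min = min(x), max = max(x),
    cv = cv, iqr = unname(stats::quantile(x, 0.75) - stats::quantile(x, 0.25)),
    energy = energy, avg_power = energy / n,
    line_length = sum(abs(diff(x))),
    amplitude_integrated = sum(abs(x)),
    nonlinear_energy = teager,
    shannon_entropy = amplitude_entropy(x, entropy_bins))
}

# Shannon entropy (bits) of the amplitude histogram: `bins` equal-width bins
# over [min(x), max(x)].  Constant windows have zero entropy by convention.
amplitude_entropy <- function(x, bins = 100L) {
  r <- range(x)
  if (r[1] == r[2]) return(0)
  cuts <- seq(r[1], r[2], length.out = bins + 1L)
  counts <- tabulate(findInterval(x, cuts, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  p <- counts[counts > 0] / length(x)
  -sum(p * log2(p))
}

#' Welch power spectral density estimate
#'
#' Hann-windowed segments with 50% overlap, averaged one-sided periodograms.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length (clamped to `length(x)`).
#' @return List with `freq` (Hz) and `psd` (power per Hz), DC bin included.
#' @export
welch_psd <- function(x, fs, nperseg = 256L) {
  sg_assert(fs > 0, "fs must be positive")
  n <- length(x)
  nperseg <- min(as.integer(nperseg), n)
  sg_assert(nperseg >= 8L, "signal too short for a PSD estimate")
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nperseg) - 1L) / (nperseg - 1L))  # Hann
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + nperseg - 1L)]
    (seg - mean(seg)) * w           # constant detrend per segment
  }, numeric(nperseg))
  spec <- Mod(stats::mvfft(segs))^2
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nperseg %/% 2L + 1L
  psd <- rowMeans(spec[seq_len(nfreq), , drop = FALSE]) * scale
  # one-sided: double all bins except DC (and Nyquist for even nperseg)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nperseg %% 2L == 0L) dbl[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1L) * fs / nperseg, psd = psd * dbl)
}

#' Spectral features of a single-channel window
#'
#' Both profiles return total power (DC excluded) and spectral entropy
#' (bits, over the normalized non-DC PSD bins); the extended profile adds
#' the delta/theta/alpha/beta/gamma band powers (gamma capped at `fs/2`).
#'
#' @param x Numeric window.
#' @param fs Sampling rate in Hz.
#' @param spec A [feature_spec()].
#' @return Named numeric vector.
#' @export
spectral_features <- function(x, fs, spec = feature_spec()) {
  p <- welch_psd(x, fs, spec$nperseg)
  keep <- p$freq > 0
  psd <- p$psd[keep]; freq <- p$freq[keep]
  total <- sum(psd)
  sentropy <- if (total > 0) {
    q <- psd / total; q <- q[q > 0]
    -sum(q * log2(q))
  } else 0
  out <- c(total_power = total, spectral_entropy = sentropy)
  if (spec$profile == "extended") {
    bp <- vapply(spec$band_edges, function(b) {
      hi <- min(b[2], fs / 2)
      sum(psd[freq >= b[1] & freq < hi])
    }, 0)
    names(bp) <- paste0("bp_", names(spec$band_edges))
    out <- c(out, bp)
  }
  out
}

#' Full per-channel feature vector
#'
#' Concatenation statistical || wavelet || spectral in a fixed documented
#' order; the `"compact19"` profile yields exactly 19 entries.
#'
#' @param x Single-channel window.
#' @param fs Sampling rate in Hz.
#' @param spec A [feature_spec()].
#' @return Named numeric vector.
#' @export
per_channel_vector <- function(x, fs, spec = feature_spec()) {
  c(statistical_features(x, spec$entropy_bins),
    dwt_features(x, spec),
    spectral_features(x, fs, spec))
}

#' Aggregate per-channel feature vectors into one row
#'
#' Cross-channel mean of every feature followed by the cross-channel
#' population variance of every feature; with the compact19 profile this is
#' the 38-column window representation.
#'
#' @param per_channel Matrix `n_channels x n_features`.
#' @return Numeric vector of length `2 * n_features`, names prefixed
#'   `mean_` / `var_`.
#' @export
aggregate_channels <- function(per_channel) {
  per_channel <- as.matrix(per_channel)
  sg_assert(nrow(per_channel) >= 1L, "need at least one channel")
  mu <- colMeans(per_channel)
  va <- colMeans(sweep(per_channel, 2L, mu)^2)   # population variance
  nm <- colnames(per_channel) %||% paste0("f", seq_along(mu))
  stats::setNames(c(mu, va), c(paste0("mean_", nm), paste0("var_", nm)))
}

#' Extract the aggregated feature matrix of a window set
#'
#' @param ws A `window_set` from [segment_windows()].
#' @param spec A [feature_spec()].
#' @return Object of class `feature_matrix`: `X` (`n_windows x n_features`),
#'   `y` (binary labels), `feature_names`, `start_times`, `fs`, `window_s`,
#'   `overlap_frac`, and an initially empty `scaler_state`.
#' @export
window_features <- function(ws, spec = feature_spec()) {
  sg_assert(inherits(ws, "window_set"), "ws must be a window_set")
  n <- length(ws$labels)
  nch <- dim(ws$windows)[2]
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    pc <- t(vapply(seq_len(nch), function(ch)
      per_channel_vector(ws$windows[k, ch, ], ws$fs, spec),
      per_channel_vector(ws$windows[k, 1L, ], ws$fs, spec)))
    rows[[k]] <- aggregate_channels(pc)
  }
  X <- do.call(rbind, rows)
  sg_assert(all(is.finite(X)), "non-finite feature values produced")
  structure(list(X = X, y = ws$labels, feature_names = colnames(X),
                 start_times = ws$start_times, fs = ws$fs,
                 window_s = ws$window_s, overlap_frac = ws$overlap_frac,
                 scaler_state = NULL, spec = spec),
            class = "feature_matrix")
}

#' Combine feature matrices from several recordings
#'
#' Rows keep their within-recording temporal order; `recording` indices and
#' absolute start times are tracked so the node sequence stays meaningful.
#'
#' @param fms List of `feature_matrix` objects.
#' @return A single `feature_matrix` with a `recording` field.
#' @export
bind_feature_matrices <- function(fms) {
  sg_assert(length(fms) >= 1L, "need at least one feature matrix")
  X <- do.call(rbind, lapply(fms, `[[`, "X"))
  out <- fms[[1L]]
  out$X <- X
  out$y <- unlist(lapply(fms, `[[`, "y"))
  out$start_times <- unlist(lapply(fms, `[[`, "start_times"))
  out$recording <- rep(seq_along(fms),
                       vapply(fms, function(f) length(f$y), 0L))
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features (%d ictal)%s\n",
              nrow(x$X), ncol(x$X), sum(x$y),
              if (is.null(x$scaler_state)) "" else ", scaled"))
  invisible(x)
}

#' Fit a per-feature min-max scaler on training rows
#'
#' @param X_train Numeric matrix of training rows only.
#' @return Object of class `minmax_scaler` with per-feature `min`/`max`.
#' @export
fit_scaler <- function(X_train) {
  X_train <- as.matrix(X_train)
  structure(list(min = apply(X_train, 2L, min),
                 max = apply(X_train, 2L, max)),
            class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' Maps each feature to `[0, 1]` over the training range; features constant
#' in training map to 0.5; out-of-range test values extrapolate (no
#' clipping).
#'
#' @param X Numeric matrix (or vector treated as one row).
#' @param state A `minmax_scaler` from [fit_scaler()].
#' @return Scaled matrix.
#' @export
apply_scaler <- function(X, state) {
  if (!inherits(state, "minmax_scaler"))
    sg_stop("scaler has not been fitted", "seizgraph_state_error")
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  rng <- state$max - state$min
  const <- rng == 0
  out <- sweep(sweep(X, 2L, state$min), 2L, ifelse(const, 1, rng), "/")
  out[, const] <- 0.5
  out
}

#' Write a feature table to CSV
#'
#' Columns: `window_start_s`, `label`, then one column per feature; an
#' `is_synthetic` column is appended when present.
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  df <- data.frame(window_start_s = fm$start_times, label = fm$y,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(fm$X, check.names = FALSE))
  if (!is.null(fm$is_synthetic)) df$is_synthetic <- fm$is_synthetic
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_csv()]
#'
#' @param path CSV path.
#' @return A `feature_matrix`.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  syn <- df$is_synthetic
  keep <- setdiff(names(df), c("window_start_s", "label", "is_synthetic"))
  structure(list(X = as.matrix(df[, keep, drop = FALSE]),
                 y = df$label, feature_names = keep,
                 start_times = df$window_start_s,
                 is_synthetic = syn, scaler_state = NULL),
            class = "feature_matrix")
}
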