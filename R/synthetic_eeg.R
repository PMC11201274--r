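#' Simulation configuration for synthetic multichannel EEG
#'
#' Describes a synthetic scalp EEG recording: stationary background made of
#' band-limited oscillations (delta/theta/alpha/beta, random phase) plus
#' 1/f ("pink") noise, and, inside each annotated seizure interval, a
#' spike-and-wave train at `sw_frequency` (a narrow Gaussian spike followed
#' by a half-sine slow wave each cycle) together with band-limited
#' high-frequency burst noise.  The generator makes no claim of
#' physiological realism; it reproduces the two signatures the detection
#' pipeline keys on — rhythmic ~3 Hz high-amplitude discharges and excess
#' high-frequency power during ictal spans.
#'
#' @param duration_s Recording length in seconds (integer, whole seconds).
#' @param fs Sampling rate in Hz (default 256).
#' @param n_channels Number of channels (default 10).
#' @param seizure_intervals Two-column matrix or list of `c(start_s, end_s)`
#'   pairs, non-overlapping, inside `[0, duration_s]`.
#' @param background_band_amplitudes Named numeric vector of sinusoid
#'   amplitudes in microvolts for bands delta (0.5-4 Hz), theta (4-8),
#'   alpha (8-13), beta (13-30).
#' @param pink_noise_scale RMS amplitude of the 1/f noise floor, microvolts.
#' @param sw_frequency Spike-and-wave repetition rate in Hz (default 3).
#' @param sw_amplitude_gain Dimensionless gain (>= 1) applied to the 100 uV
#'   base spike-and-wave template.
#' @param hf_burst_scale RMS amplitude in microvolts of 20-60 Hz burst noise
#'   added during seizures.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return An object of class `sim_config`.
#' @seealso [simulate_recording()]
#' @export
sim_config <- function(duration_s,
                       fs = 256,
                       n_channels = 10,
                       seizure_intervals = NULL,
                       background_band_amplitudes = c(delta = 20, theta = 10,
                                                      alpha = 15, beta = 5),
                       pink_noise_scale = 10,
                       sw_frequency = 3.0,
                       sw_amplitude_gain = 2.0,
                       hf_burst_scale = 15,
                       seed = 1L) {
  sg_assert(is.numeric(duration_s) && length(duration_s) == 1L && duration_s > 0,
            "duration_s must be a positive scalar")
  sg_assert(fs > 0 && fs == as.integer(fs), "fs must be a positive integer")
  sg_assert(n_channels >= 1, "n_channels must be >= 1")
  sg_assert(sw_amplitude_gain >= 1, "sw_amplitude_gain must be >= 1")
  sg_assert(all(background_band_amplitudes >= 0) && pink_noise_scale >= 0 &&
              hf_burst_scale >= 0, "amplitudes must be non-negative")
  iv <- check_intervals(seizure_intervals, duration_s)
  # Nyquist guard: highest synthesized frequency is the top of the
  # high-frequency burst band (60 Hz) or beta (30 Hz).
  f_max <- max(30, if (length(iv) && hf_burst_scale > 0) 60 else 0,
               sw_frequency)
  sg_assert(fs > 2 * f_max,
            "fs must exceed twice the highest synthesized frequency")
  structure(list(
    duration_s = as.numeric(duration_s), fs = as.integer(fs),
    n_channels = as.integer(n_channels), seizure_intervals = iv,
    background_band_amplitudes = background_band_amplitudes,
    pink_noise_scale = pink_noise_scale, sw_frequency = sw_frequency,
    sw_amplitude_gain = sw_amplitude_gain, hf_burst_scale = hf_burst_scale,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Default bipolar montage labels: the nine unique channels of the standard
# frontotemporal/tempoparietal selection plus P8-O2 as the tenth slot.
default_montage <- function(n = 10) {
  base <- c("T8-P8", "FT10-T8", "FT9-FT10", "F8-T8", "FP2-F8",
            "P4-O2", "C4-P4", "F4-C4", "FP1-F7", "P8-O2")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("CH%02d", seq_len(n - length(base))))
}

#' Construct a raw multichannel recording object
#'
#' @param signal Numeric matrix, channels in rows, samples in columns (uV).
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per channel.
#' @param seizure_intervals Two-column matrix / list of `(start_s, end_s)`.
#' @param subject_id Free-text identifier.
#' @return Object of class `raw_recording`.
#' @export
raw_recording <- function(signal, fs, channel_labels,
                          seizure_intervals = NULL, subject_id = "synthetic") {
  signal <- as.matrix(signal)
  sg_assert(length(channel_labels) == nrow(signal),
            "channel_labels must match the number of signal rows")
  dur <- ncol(signal) / fs
  iv <- check_intervals(seizure_intervals, dur)
  structure(list(signal = signal, fs = as.numeric(fs),
                 channel_labels = as.character(channel_labels),
                 seizure_intervals = iv, subject_id = subject_id),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s: %d channels x %d samples @ %g Hz (%.1f s), %d seizure interval(s)\n",
              x$subject_id, nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs, nrow(x$seizure_intervals)))
  invisible(x)
}

recording_duration <- function(rec) ncol(rec$signal) / rec$fs

#' Per-sample ictal mask of a recording
#'
#' @param rec A `raw_recording`.
#' @return Logical vector, one entry per sample, `TRUE` inside a seizure.
#' @export
ictal_mask <- function(rec) {
  t <- (seq_len(ncol(rec$signal)) - 1) / rec$fs
  m <- rep(FALSE, length(t))
  iv <- rec$seizure_intervals
  for (k in seq_len(nrow(iv))) m <- m | (t >= iv[k, 1] & t < iv[k, 2])
  m
}

# One cycle of the spike-and-wave template, unit peak amplitude.
# Phase tau in [0, T): narrow Gaussian spike early in the cycle, then a
# half-sine slow wave of opposite sign occupying the remainder.
spike_wave_template <- function(tau, period) {
  spike_c <- 0.06            # spike centre (s)
  spike_sd <- 0.015          # spike width (s)
  wave_on <- 0.12            # slow wave onset within cycle (s)
  spike <- exp(-(tau - spike_c)^2 / (2 * spike_sd^2))
  wave <- ifelse(tau >= wave_on,
                 0.6 * sin(pi * (tau - wave_on) / (period - wave_on)), 0)
  spike - wave
}

# 1/f-amplitude noise via spectral shaping of white noise, unit RMS.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- c(1, seq_len(n - 1))            # DC kept at the first bin's weight
  amp <- 1 / sqrt(pmin(k, n - k + 1))  # symmetric 1/sqrt(f) shaping
  x <- Re(stats::fft(W * amp, inverse = TRUE)) / n
  x / sd(x)
}

# Band-limited white noise restricted to [f_lo, f_hi] Hz, unit RMS.
bandlimited_noise <- function(n, fs, f_lo, f_hi) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                 # two-sided frequency axis
  W[f < f_lo | f > f_hi] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) x else x / s
}

#' Simulate a labeled multichannel EEG recording
#'
#' Background = band oscillations with per-channel random frequency/phase +
#' pink noise.  Inside each seizure interval a shared spike-and-wave train
#' (per-channel gain jitter in \[0.8, 1.2\]) and 20-60 Hz burst noise are
#' added.  All randomness flows from `config$seed`; equal configs give
#' bit-identical signals.
#'
#' @param config A [sim_config()].
#' @return A [raw_recording()].
#' @export
simulate_recording <- function(config) {
  sg_assert(inherits(config, "sim_config"), "config must be a sim_config")
  with_rng(config$seed, {
    fs <- config$fs
    n <- as.integer(round(config$duration_s * fs))
    t <- (seq_len(n) - 1) / fs
    bands <- list(delta = c(0.5, 4), theta = c(4, 8),
                  alpha = c(8, 13), beta = c(13, 30))
    amps <- config$background_band_amplitudes
    sig <- matrix(0, nrow = config$n_channels, ncol = n)
    for (ch in seq_len(config$n_channels)) {
      x <- numeric(n)
      for (b in names(bands)) {
        a <- if (b %in% names(amps)) amps[[b]] else 0
        if (a > 0) {
          f <- stats::runif(1, bands[[b]][1], bands[[b]][2])
          ph <- stats::runif(1, 0, 2 * pi)
          x <- x + a * sin(2 * pi * f * t + ph)
        }
      }
      if (config$pink_noise_scale > 0)
        x <- x + config$pink_noise_scale * pink_noise(n)
      sig[ch, ] <- x
    }
    iv <- config$seizure_intervals
    if (nrow(iv) > 0) {
      period <- 1 / config$sw_frequency
      gains <- stats::runif(config$n_channels, 0.8, 1.2)
      for (k in seq_len(nrow(iv))) {
        idx <- which(t >= iv[k, 1] & t < iv[k, 2])
        if (!length(idx)) next
        tau <- (t[idx] - iv[k, 1]) %% period
        train <- 100 * config$sw_amplitude_gain *
          spike_wave_template(tau, period)
        hf <- if (config$hf_burst_scale > 0)
          config$hf_burst_scale * bandlimited_noise(length(idx), fs, 20, 60)
        else 0
        for (ch in seq_len(config$n_channels))
          sig[ch, idx] <- sig[ch, idx] + gains[ch] * train + hf
      }
    }
    raw_recording(sig, fs, default_montage(config$n_channels),
                  iv, subject_id = sprintf("sim-seed%d", config$seed))
  })
}
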