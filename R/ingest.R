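# Ingest stage: channel subset selection, optional resampling to a common
# rate, and segmentation into fixed-length overlapping labeled windows.

#' Default 10-channel bipolar selection
#'
#' The frontotemporal/tempoparietal montage used for channel reduction.  The
#' published list names "T8-P8" twice; this default keeps the nine unique
#' names and lets callers supply a tenth via `extra`.
#'
#' @param extra Optional additional channel name(s) appended to the nine.
#' @return Character vector of channel names.
#' @export
default_channel_selection <- function(extra = NULL) {
  base <- c("T8-P8", "FT10-T8", "FT9-FT10", "F8-T8", "FP2-F8",
            "P4-O2", "C4-P4", "F4-C4", "FP1-F7")
  unique(c(base, extra))
}

#' Select and reorder channels of a recording
#'
#' Matching is case-insensitive; the output channel order follows `names`.
#'
#' @param rec A [raw_recording()].
#' @param names Channel names to keep, in the desired order.
#' @return A [raw_recording()] with the requested channels.
#' @export
select_channels <- function(rec, names) {
  sg_assert(inherits(rec, "raw_recording"), "rec must be a raw_recording")
  idx <- match(tolower(names), tolower(rec$channel_labels))
  if (anyNA(idx))
    sg_stop(paste0("channel(s) not found: ",
                   paste(names[is.na(idx)], collapse = ", ")),
            "seizgraph_lookup_error")
  raw_recording(rec$signal[idx, , drop = FALSE], rec$fs,
                rec$channel_labels[idx], rec$seizure_intervals,
                rec$subject_id)
}

#' Polyphase-resample a recording to a target rate
#'
#' @param rec A [raw_recording()].
#' @param target_fs Target sampling rate in Hz (default 256).
#' @return A [raw_recording()] at `target_fs`.
#' @export
resample_recording <- function(rec, target_fs = 256) {
  sg_assert(target_fs > 0, "target_fs must be positive")
  if (rec$fs == target_fs) return(rec)
  # reduced rational rate ratio for polyphase resampling
  frac <- as.integer(c(target_fs, rec$fs) / gcd_int(target_fs, rec$fs))
  out <- t(apply(rec$signal, 1L, function(x)
    signal::resample(x, p = frac[1], q = frac[2])))
  raw_recording(out, target_fs, rec$channel_labels,
                rec$seizure_intervals, rec$subject_id)
}

gcd_int <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' Segment a recording into overlapping labeled windows
#'
#' Windows are `window_s` seconds long; consecutive windows share
#' `overlap_frac` of their length, i.e. the stride is
#' `window_s * (1 - overlap_frac)`.  A trailing span shorter than a full
#' window is dropped.  Window `k` covers `[k*stride, k*stride + window_s)`
#' and is labeled ictal (1) when its intersection with any seizure interval
#' exceeds `label_min_overlap_s` seconds (default: any positive overlap).
#'
#' @param rec A [raw_recording()].
#' @param window_s Window length in seconds (default 30).
#' @param overlap_frac Fraction of window shared by consecutive windows,
#'   in `[0, 1)` (default 0.30).
#' @param label_min_overlap_s Minimum seizure overlap (seconds, exclusive
#'   threshold) for an ictal label.
#' @return An object of class `window_set` with fields `windows`
#'   (`n_windows x n_channels x window_samples` array), `start_times`,
#'   `labels`, `fs`, `window_s`, `overlap_frac`.
#' @export
segment_windows <- function(rec, window_s = 30, overlap_frac = 0.30,
                            label_min_overlap_s = 0) {
  sg_assert(inherits(rec, "raw_recording"), "rec must be a raw_recording")
  sg_assert(overlap_frac >= 0 && overlap_frac < 1,
            "overlap_frac must lie in [0, 1)")
  dur <- recording_duration(rec)
  if (dur < window_s)
    sg_stop("recording shorter than one window", "seizgraph_empty_result_error")
  stride <- window_s * (1 - overlap_frac)
  n_win <- floor((dur - window_s) / stride) + 1L
  starts <- (seq_len(n_win) - 1L) * stride
  wlen <- as.integer(round(window_s * rec$fs))
  nch <- nrow(rec$signal)

  windows <- array(0, dim = c(n_win, nch, wlen))
  for (k in seq_len(n_win)) {
    i0 <- as.integer(round(starts[k] * rec$fs))
    windows[k, , ] <- rec$signal[, (i0 + 1L):(i0 + wlen), drop = FALSE]
  }
  labels <- window_labels(starts, window_s, rec$seizure_intervals,
                          label_min_overlap_s)
  structure(list(windows = windows, start_times = starts, labels = labels,
                 fs = rec$fs, window_s = window_s, overlap_frac = overlap_frac),
            class = "window_set")
}

window_labels <- function(starts, window_s, intervals, label_min_overlap_s) {
  labels <- integer(length(starts))
  for (k in seq_len(nrow(intervals))) {
    ov <- pmin(starts + window_s, intervals[k, 2]) -
      pmax(starts, intervals[k, 1])
    labels[ov > label_min_overlap_s] <- 1L
  }
  labels
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %g s (overlap %g%%), %d ictal\n",
              length(x$labels), x$window_s, 100 * x$overlap_frac,
              sum(x$labels)))
  invisible(x)
}
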