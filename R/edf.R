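# Minimal EDF (European Data Format) codec: 16-bit integer samples, one
# one-second data record per signal per second, fixed physical range
# +/-1000 uV.  Seizure annotations travel in a plain-text sidecar
# (`<path>.seizures.tsv`, lines `start_s<TAB>end_s`), mirroring the style of
# CHB-MIT summary files rather than EDF+ annotation signals.

EDF_PHYS_MIN <- -1000
EDF_PHYS_MAX <- 1000
EDF_DIG_MIN <- -32768L
EDF_DIG_MAX <- 32767L

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  formatC(s, width = width, flag = "-")
}

edf_sidecar_path <- function(path) paste0(path, ".seizures.tsv")

#' Write a recording to an EDF file with a plain-text annotation sidecar
#'
#' Samples are quantized to 16 bits over a fixed physical range of
#' +/-1000 microvolts (values outside are clipped); each data record holds
#' one second per signal.  Seizure intervals are written to
#' `<path>.seizures.tsv` as tab-separated `start_s  end_s` lines.
#'
#' @param rec A [raw_recording()]; `fs` must be a whole number.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  sg_assert(inherits(rec, "raw_recording"), "rec must be a raw_recording")
  sg_assert(nrow(rec$signal) >= 1L, "recording has no channels")
  sg_assert(all(is.finite(rec$signal)), "signal must be finite")
  fs <- rec$fs
  sg_assert(fs == as.integer(fs), "fs must be an integer for EDF export")
  fs <- as.integer(fs)
  ns <- nrow(rec$signal)
  n_rec <- ncol(rec$signal) %/% fs
  sg_assert(n_rec >= 1L, "recording shorter than one data record (1 s)")
  if (n_rec * fs != ncol(rec$signal))
    warning("trailing partial second dropped in EDF export")

  con <- tryCatch(suppressWarnings(file(path, "wb")),
                  error = function(e) sg_stop(
                    paste0("cannot open '", path, "' for writing"),
                    "seizgraph_io_error"))
  on.exit(close(con))

  hdr <- paste0(
    pad_field("0", 8),
    pad_field(rec$subject_id, 80),
    pad_field("Startdate 01-JAN-2000 seizgraph", 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(256 + 256 * ns, 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),
    pad_field(ns, 4)
  )
  per_sig <- function(vals, width) paste0(vapply(vals, pad_field, "", width))
  hdr <- paste0(
    hdr,
    paste(per_sig(rec$channel_labels, 16), collapse = ""),
    paste(per_sig(rep("", ns), 80), collapse = ""),
    paste(per_sig(rep("uV", ns), 8), collapse = ""),
    paste(per_sig(rep(EDF_PHYS_MIN, ns), 8), collapse = ""),
    paste(per_sig(rep(EDF_PHYS_MAX, ns), 8), collapse = ""),
    paste(per_sig(rep(EDF_DIG_MIN, ns), 8), collapse = ""),
    paste(per_sig(rep(EDF_DIG_MAX, ns), 8), collapse = ""),
    paste(per_sig(rep("", ns), 80), collapse = ""),
    paste(per_sig(rep(fs, ns), 8), collapse = ""),
    paste(per_sig(rep("", ns), 32), collapse = "")
  )
  writeBin(charToRaw(hdr), con)

  scale <- (EDF_DIG_MAX - EDF_DIG_MIN) / (EDF_PHYS_MAX - EDF_PHYS_MIN)
  x <- pmin(pmax(rec$signal, EDF_PHYS_MIN), EDF_PHYS_MAX)
  dig <- matrix(as.integer(round((x - EDF_PHYS_MIN) * scale + EDF_DIG_MIN)),
                nrow = ns)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    # signals are stored sequentially within each record
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con,
             size = 2L, endian = "little")
  }

  iv <- rec$seizure_intervals
  utils::write.table(data.frame(start_s = iv[, 1], end_s = iv[, 2]),
                     edf_sidecar_path(path), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_header_field <- function(raw, offset, width) {
  trimws(rawToChar(raw[(offset + 1L):(offset + width)]))
}

#' Read an EDF file (and its seizure-annotation sidecar)
#'
#' Supports the 16-bit continuous EDF layout written by [write_edf()] and
#' standard single-rate EDF recordings.  If `annotation_path` exists (default
#' `<path>.seizures.tsv`), seizure intervals are parsed from its
#' `start_s<TAB>end_s` lines; otherwise the interval list is empty.
#'
#' @param path EDF file path.
#' @param annotation_path Optional sidecar path.
#' @return A [raw_recording()].
#' @export
read_edf <- function(path, annotation_path = NULL) {
  sg_assert(file.exists(path), paste0("no such EDF file: ", path),
            "seizgraph_io_error")
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 256L)
    sg_stop("malformed EDF: truncated header", "seizgraph_parse_error")
  header_bytes <- suppressWarnings(as.integer(read_header_field(raw, 184, 8)))
  n_rec <- suppressWarnings(as.integer(read_header_field(raw, 236, 8)))
  rec_dur <- suppressWarnings(as.numeric(read_header_field(raw, 244, 8)))
  ns <- suppressWarnings(as.integer(read_header_field(raw, 252, 4)))
  if (any(is.na(c(header_bytes, n_rec, rec_dur, ns))) || ns < 1L)
    sg_stop("malformed EDF: unparsable header fields", "seizgraph_parse_error")
  if (length(raw) < header_bytes)
    sg_stop("malformed EDF: header shorter than advertised",
            "seizgraph_parse_error")

  # per-signal field offsets (in bytes) within the signal header block
  off <- c(label = 0, transducer = 16, dim = 96, pmin = 104, pmax = 112,
           dmin = 120, dmax = 128, prefilter = 136, nsamp = 216)
  fld <- function(name, width) {
    vapply(seq_len(ns) - 1L, function(i)
      read_header_field(raw, 256 + off[[name]] * ns + i * width, width), "")
  }
  labels <- fld("label", 16)
  pmin <- as.numeric(fld("pmin", 8)); pmax <- as.numeric(fld("pmax", 8))
  dmin <- as.numeric(fld("dmin", 8)); dmax <- as.numeric(fld("dmax", 8))
  nsamp <- as.integer(fld("nsamp", 8))
  if (any(is.na(c(pmin, pmax, dmin, dmax, nsamp))))
    sg_stop("malformed EDF: unparsable signal headers", "seizgraph_parse_error")
  fs_all <- nsamp / rec_dur
  if (length(unique(fs_all)) != 1L)
    sg_stop("unsupported EDF: signals have differing sampling rates",
            "seizgraph_unsupported_format_error")
  fs <- fs_all[1]

  body <- raw[(header_bytes + 1L):length(raw)]
  vals <- readBin(body, "integer", n = length(body) %/% 2L,
                  size = 2L, endian = "little", signed = TRUE)
  per_rec <- sum(nsamp)
  if (length(vals) < n_rec * per_rec)
    sg_stop("malformed EDF: data shorter than advertised",
            "seizgraph_parse_error")
  sig <- matrix(0, nrow = ns, ncol = n_rec * nsamp[1])
  for (r in seq_len(n_rec)) {
    block <- vals[((r - 1L) * per_rec + 1L):(r * per_rec)]
    for (s in seq_len(ns)) {
      seg <- block[(sum(nsamp[seq_len(s - 1L)]) + 1L):sum(nsamp[seq_len(s)])]
      cols <- ((r - 1L) * nsamp[s] + 1L):(r * nsamp[s])
      sig[s, cols] <- (seg - dmin[s]) / (dmax[s] - dmin[s]) *
        (pmax[s] - pmin[s]) + pmin[s]
    }
  }

  ann <- annotation_path %||% edf_sidecar_path(path)
  intervals <- if (file.exists(ann)) read_seizure_sidecar(ann) else NULL
  raw_recording(sig, fs, labels, intervals,
                subject_id = read_header_field(raw, 8, 80))
}

#' Parse a tab-separated seizure annotation sidecar
#'
#' @param path File with one `start_s<TAB>end_s` line per seizure.
#' @return Two-column numeric matrix (possibly 0-row).
#' @export
read_seizure_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(as_interval_matrix(NULL))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  iv <- do.call(rbind, lapply(parts, function(p) as.numeric(p[1:2])))
  sg_assert(all(is.finite(iv)), "unparsable annotation sidecar",
            "seizgraph_parse_error")
  as_interval_matrix(iv)
}
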