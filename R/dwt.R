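# Periodized discrete wavelet transform with Daubechies filters.
# Analysis low/high-pass pairs for db4/db8 (4 and 8 vanishing moments),
# standard orthonormal coefficients to full double precision.

DB_FILTERS <- list(
  db8 = list(
    lo = c(-0.00011747678412476953, 0.0006754494064505693,
           -0.00039174037337694705, -0.004870352993451574,
           0.008746094047405777, 0.013981027917398282,
           -0.044088253930794755, -0.017369301001807547,
           0.12874742662047847, 0.0004724845739132828,
           -0.2840155429615469, -0.015829105256349306,
           0.5853546836542067, 0.6756307362972898,
           0.31287159091429995, 0.05441584224310401),
    hi = c(-0.05441584224310401, 0.31287159091429995,
           -0.6756307362972898, 0.5853546836542067,
           0.015829105256349306, -0.2840155429615469,
           -0.0004724845739132828, 0.12874742662047847,
           0.017369301001807547, -0.044088253930794755,
           -0.013981027917398282, 0.008746094047405777,
           0.004870352993451574, -0.00039174037337694705,
           -0.0006754494064505693, -0.00011747678412476953)
  ),
  db4 = list(
    lo = c(-0.010597401784997278, 0.032883011666982945,
           0.030841381835986965, -0.18703481171888114,
           -0.02798376941698385, 0.6308807679295904,
           0.7148465705525415, 0.23037781330885523),
    hi = c(-0.23037781330885523, 0.7148465705525415,
           -0.6308807679295904, -0.02798376941698385,
           0.18703481171888114, 0.030841381835986965,
           -0.032883011666982945, -0.010597401784997278)
  )
)

# One periodized analysis step: circular correlation with the filter,
# downsampled by two.  With orthonormal Daubechies pairs and even n this is
# an orthogonal map, so sum(a^2) + sum(d^2) == sum(x^2) exactly (up to
# floating point).
dwt_step <- function(x, lo, hi) {
  n <- length(x)
  sg_assert(n %% 2L == 0L, "periodized DWT needs an even signal length")
  L <- length(lo)
  idx <- (outer(0:(L - 1L), seq(0L, n - 2L, by = 2L), "+") %% n) + 1L
  xm <- matrix(x[idx], nrow = L)
  list(a = as.vector(lo %*% xm), d = as.vector(hi %*% xm))
}

#' Multilevel periodized discrete wavelet transform
#'
#' Decomposes a signal with a Daubechies wavelet using periodization
#' boundary handling, which makes the transform orthogonal: the summed
#' squared coefficients equal the signal energy whenever the length is
#' divisible by `2^levels`.
#'
#' @param x Numeric signal.
#' @param wavelet `"db8"` (default, 8 vanishing moments) or `"db4"`.
#' @param levels Number of decomposition levels (default 5).
#' @return List with `approximation` (coarsest-scale coefficients) and
#'   `details` (list of detail coefficient vectors, level 1 = finest).
#' @export
dwt_periodized <- function(x, wavelet = "db8", levels = 5L) {
  if (!wavelet %in% names(DB_FILTERS))
    sg_stop(paste0("unsupported wavelet: ", wavelet),
            "seizgraph_validation_error")
  sg_assert(levels >= 1L, "levels must be >= 1")
  f <- DB_FILTERS[[wavelet]]
  sg_assert(length(x) >= length(f$lo),
            "window shorter than the wavelet filter")
  details <- vector("list", levels)
  a <- as.numeric(x)
  for (l in seq_len(levels)) {
    st <- dwt_step(a, f$lo, f$hi)
    details[[l]] <- st$d
    a <- st$a
  }
  list(approximation = a, details = details)
}

#' Wavelet features of a single-channel window
#'
#' Compact profile: mean of the coarsest approximation coefficients and the
#' standard deviation of all detail coefficients pooled across levels.
#' Extended profile: per-level detail standard deviations and per-subband
#' energies (finest detail first, approximation last) in addition to the
#' approximation mean.
#'
#' @param x Numeric window.
#' @param spec A [feature_spec()].
#' @return Named numeric vector of wavelet features.
#' @export
dwt_features <- function(x, spec = feature_spec()) {
  res <- dwt_periodized(x, spec$wavelet, spec$levels)
  all_d <- unlist(res$details)
  pooled_sd <- if (length(all_d) > 1L) stats::sd(all_d) else 0
  if (spec$profile == "compact19") {
    c(dwt_approx_mean = mean(res$approximation),
      dwt_detail_sd = pooled_sd)
  } else {
    per_sd <- vapply(res$details, function(d)
      if (length(d) > 1L) stats::sd(d) else 0, 0)
    energies <- c(vapply(res$details, function(d) sum(d^2), 0),
                  sum(res$approximation^2))
    names(per_sd) <- sprintf("dwt_detail_sd_l%d", seq_along(per_sd))
    names(energies) <- c(sprintf("dwt_energy_d%d", seq_along(res$details)),
                         "dwt_energy_a")
    c(dwt_approx_mean = mean(res$approximation), per_sd, energies)
  }
}
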