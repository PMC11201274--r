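test_that("statistical features match hand arithmetic on [1,2,3,4]", {
  f <- statistical_features(c(1, 2, 3, 4))
  expect_equal(f[["mean"]], 2.5)
  expect_equal(f[["min"]], 1)
  expect_equal(f[["max"]], 4)
  expect_equal(f[["energy"]], 30)
  expect_equal(f[["line_length"]], 3)
  expect_equal(f[["avg_power"]], 7.5)
  expect_equal(f[["amplitude_integrated"]], 10)
  # Teager operator: mean(2^2 - 1*3, 3^2 - 2*4) = mean(1, 1)
  expect_equal(f[["nonlinear_energy"]], 1.0)
  expect_equal(f[["variance"]], 1.25)     # population variance
})

test_that("constant windows collapse the dispersion features", {
  f <- statistical_features(rep(2.5, 100))
  expect_equal(f[["variance"]], 0)
  expect_equal(f[["line_length"]], 0)
  expect_equal(f[["shannon_entropy"]], 0)
  expect_equal(f[["skewness"]], 0)
  expect_equal(f[["iqr"]], 0)
  expect_error(statistical_features(c(1, 2)), "at least 3")
})

test_that("zero-mean windows report CV 0 with a warning", {
  expect_warning(f <- statistical_features(c(-1, 0, 1)), "zero-mean")
  expect_equal(f[["cv"]], 0)
})

test_that("amplitude-histogram entropy is scale invariant", {
  withr::with_seed(1, {
    for (i in 1:5) {
      x <- rnorm(512)
      h1 <- statistical_features(x)[["shannon_entropy"]]
      h2 <- statistical_features(5.7 * x)[["shannon_entropy"]]
      expect_equal(h1, h2, tolerance = 1e-12)
    }
  })
})

test_that("the periodized db8 transform conserves energy", {
  withr::with_seed(3, {
    for (i in 1:20) {
      n <- 32 * sample(4:40, 1)
      x <- rnorm(n)
      d <- dwt_periodized(x, "db8", 5)
      coef_energy <- sum(d$approximation^2) + sum(unlist(d$details)^2)
      expect_lt(abs(coef_energy - sum(x^2)) / sum(x^2), 1e-8)
      expect_length(d$approximation, n / 32)
    }
  })
})

test_that("wavelet features vanish on a zero window and reject bad wavelets", {
  f <- dwt_features(numeric(320))
  expect_true(all(f == 0))
  expect_error(dwt_periodized(rnorm(64), "sym4"), "unsupported wavelet")
})

test_that("low-pass filtering shrinks the pooled detail deviation", {
  withr::with_seed(9, {
    x <- rnorm(1024)
    smooth <- stats::filter(x, rep(1 / 8, 8), sides = 2)
    smooth[is.na(smooth)] <- 0
    sd_raw <- dwt_features(x)[["dwt_detail_sd"]]
    sd_smooth <- dwt_features(as.numeric(smooth))[["dwt_detail_sd"]]
    expect_gt(sd_raw, sd_smooth)
  })
})

test_that("a 10 Hz tone concentrates power in the alpha band", {
  t <- (0:2047) / 256
  x <- sin(2 * pi * 10 * t)
  sp <- spectral_features(x, 256, feature_spec("extended"))
  bands <- sp[grep("^bp_", names(sp))]
  expect_equal(names(which.max(bands)), "bp_alpha")
})

test_that("a constant signal has (near) zero band power", {
  sp <- spectral_features(rep(3, 1024), 256, feature_spec("extended"))
  expect_lt(sum(sp[grep("^bp_", names(sp))]), 1e-12)
})

test_that("white-noise spectral entropy approaches the flat-spectrum limit", {
  withr::with_seed(4, {
    x <- rnorm(256 * 30)
    sp <- spectral_features(x, 256)
    n_bins <- 128    # non-DC bins of a 256-point Welch segment
    expect_lt(abs(sp[["spectral_entropy"]] - log2(n_bins)) / log2(n_bins),
              0.05)
  })
})

test_that("the compact19 per-channel vector has 19 aligned named entries", {
  withr::with_seed(5, x <- rnorm(256 * 30))
  v <- per_channel_vector(x, 256)
  expect_length(v, 19)
  expect_equal(names(v)[1:15], seizgraph:::STATISTICAL_FEATURE_NAMES)
  # name/value alignment: recompute single entries independently
  expect_equal(v[["median"]], median(x))
  expect_equal(v[["energy"]], sum(x^2))
  expect_equal(v[["dwt_approx_mean"]],
               mean(dwt_periodized(x)$approximation))
  expect_equal(v[["total_power"]],
               spectral_features(x, 256)[["total_power"]])
})

test_that("zero windows produce the degenerate compact19 vector", {
  suppressWarnings(v <- per_channel_vector(numeric(7680), 256))
  expect_equal(unname(v[c("variance", "line_length", "shannon_entropy",
                          "dwt_approx_mean", "dwt_detail_sd",
                          "total_power")]),
               rep(0, 6))
})

test_that("cross-channel aggregation is the mean/population-variance pair", {
  row <- aggregate_channels(rbind(c(1, 3), c(3, 5)))
  expect_equal(unname(row), c(2, 4, 1, 1))

  one <- aggregate_channels(matrix(c(1, 2, 3), 1))
  expect_equal(unname(one), c(1, 2, 3, 0, 0, 0))

  dup <- aggregate_channels(rbind(c(2, 7), c(2, 7)))
  expect_equal(unname(dup), c(2, 7, 0, 0))
})

test_that("aggregation is invariant to channel order", {
  withr::with_seed(6, M <- matrix(rnorm(5 * 19), 5))
  expect_equal(aggregate_channels(M),
               aggregate_channels(M[sample(5), ]))
})

test_that("amplitude scaling moves energy quadratically, entropy not at all", {
  withr::with_seed(7, x <- rnorm(2048))
  a <- per_channel_vector(x, 256)
  b <- per_channel_vector(3 * x, 256)
  expect_equal(b[["energy"]], 9 * a[["energy"]])
  expect_equal(b[["mean"]], 3 * a[["mean"]])
  expect_equal(b[["shannon_entropy"]], a[["shannon_entropy"]])
})

test_that("min-max scaling maps training rows into [0,1] and extrapolates", {
  X <- cbind(c(0, 2, 4), c(5, 5, 5))
  st <- fit_scaler(X)
  Xs <- apply_scaler(X, st)
  expect_equal(Xs[, 1], c(0, 0.5, 1))
  expect_equal(Xs[, 2], rep(0.5, 3))     # constant feature -> 0.5
  # below-training-minimum values pass through negative (no clipping)
  expect_equal(apply_scaler(matrix(c(-2, 5), 1), st)[1, 1], -0.5)
  expect_error(apply_scaler(X, list()), class = "seizgraph_state_error")
})

test_that("an ictal window dominates a background window in detail SD and 2-5 Hz power", {
  rec <- tiny_recording(180, rbind(c(60, 120)), seed = 12, n_channels = 2)
  fs <- rec$fs
  ictal_win <- rec$signal[1, (70 * fs + 1):(100 * fs)]
  backg_win <- rec$signal[1, (140 * fs + 1):(170 * fs)]
  expect_gt(dwt_features(ictal_win)[["dwt_detail_sd"]],
            dwt_features(backg_win)[["dwt_detail_sd"]])
  expect_gt(fft_band_power(ictal_win, fs, 2, 5),
            fft_band_power(backg_win, fs, 2, 5))
})

test_that("feature CSV round-trips the matrix, labels and names", {
  rec <- tiny_recording(72, rbind(c(30, 50)), seed = 13, n_channels = 2)
  fm <- window_features(segment_windows(rec))
  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fm, p)
  fm2 <- read_feature_csv(p)
  expect_equal(unname(fm2$X), unname(fm$X))
  expect_equal(fm2$y, fm$y)
  expect_equal(fm2$feature_names, fm$feature_names)
})
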