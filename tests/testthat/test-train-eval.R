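test_that("the shuffled split has the exact rounded sizes and partitions 1:n", {
  s <- split_dataset(100, seed = 1)
  expect_equal(lengths(s), c(train = 60L, val = 20L, test = 20L))
  s10 <- split_dataset(10, seed = 2)
  expect_equal(lengths(s10), c(train = 6L, val = 2L, test = 2L))
  for (n in c(5, 17, 101)) {
    s <- split_dataset(n, seed = 3)
    all_idx <- sort(c(s$train, s$val, s$test))
    expect_equal(all_idx, seq_len(n))
    expect_equal(length(intersect(s$train, s$val)), 0)
    expect_equal(length(intersect(s$train, s$test)), 0)
  }
  expect_error(split_dataset(3), "at least 5")
  # seeded shuffle: same seed same split, different seed different split
  expect_identical(split_dataset(50, seed = 9), split_dataset(50, seed = 9))
  expect_false(identical(split_dataset(50, seed = 9),
                         split_dataset(50, seed = 10)))
})

test_that("training separates the toy clusters and is seed-deterministic", {
  fm <- toy_feature_matrix(n = 80, seed = 21)
  cfg <- train_config(epochs = 15, patience = 10, seed = 2,
                      batch_size = 16)
  fit_b1 <- seizure_gcn(fm, head = "brf", config = cfg)
  fit_b2 <- seizure_gcn(fm, head = "brf", config = cfg)
  expect_identical(fit_b1$report$confusion, fit_b2$report$confusion)
  expect_gte(fit_b1$report$accuracy, 0.9)

  fit_l1 <- seizure_gcn(fm, head = "lstm", config = cfg)
  fit_l2 <- seizure_gcn(fm, head = "lstm", config = cfg)
  expect_identical(fit_l1$report$confusion, fit_l2$report$confusion)
  expect_identical(fit_l1$score, fit_l2$score)
})

test_that("training loss decreases over early epochs on the toy set", {
  fm <- toy_feature_matrix(n = 80, seed = 22)
  fit <- seizure_gcn(fm, head = "brf",
                     config = train_config(epochs = 5, seed = 3,
                                           batch_size = 16))
  h <- fit$history
  steps <- diff(h$train_loss[1:min(5, nrow(h))])
  expect_gte(sum(steps <= 1e-6), length(steps) - 1)
})

test_that("a zero learning rate halts training at exactly patience + 1 epochs", {
  fm <- toy_feature_matrix(n = 60, seed = 23)
  fit <- seizure_gcn(fm, head = "brf",
                     config = train_config(lr = 0, epochs = 50, patience = 4,
                                           seed = 4, batch_size = 32))
  expect_equal(nrow(fit$history), 5)
  expect_equal(fit$best_epoch, 1)
})

test_that("degenerate single-class training partitions are rejected", {
  fm <- toy_feature_matrix(n = 40, seed = 24)
  fm$y <- rep(0L, 40)
  expect_error(seizure_gcn(fm, head = "brf"), "both classes")
})

test_that("scaler and resampler state never see evaluation rows", {
  fm <- toy_feature_matrix(n = 60, seed = 25)
  cfg <- train_config(epochs = 2, seed = 5, batch_size = 32)
  idx <- split_dataset(nrow(fm$X), cfg$split, cfg$seed)

  fm_pert <- fm
  fm_pert$X[c(idx$val, idx$test), ] <-
    fm_pert$X[c(idx$val, idx$test), ] + 100

  fit_a <- seizure_gcn(fm, head = "brf", config = cfg)
  # grossly perturbed evaluation rows legitimately trip the scaling warning
  fit_b <- suppressWarnings(seizure_gcn(fm_pert, head = "brf", config = cfg))
  expect_identical(fit_a$scaler, fit_b$scaler)

  rs_cfg <- cfg$resample; rs_cfg$seed <- cfg$seed
  scl <- fit_scaler(fm$X[idx$train, ])
  rs_a <- resample_training(apply_scaler(fm$X, scl)[idx$train, ],
                            fm$y[idx$train], rs_cfg)
  rs_b <- resample_training(apply_scaler(fm_pert$X, scl)[idx$train, ],
                            fm_pert$y[idx$train], rs_cfg)
  expect_identical(rs_a, rs_b)
})

test_that("per-second probabilities average the covering windows", {
  # second 25 is covered by windows starting at 0 s and 21 s
  tr <- seizgraph:::per_second_track(c(0, 21, 42), 30, c(0.2, 0.6, 1.0), 60)
  expect_equal(tr$probability[tr$second == 25], 0.4)
  expect_equal(tr$probability[tr$second == 5], 0.2)    # only window 1
  expect_equal(tr$probability[tr$second == 45], 0.8)   # windows 2 and 3

  none <- seizgraph:::runs_to_intervals(rep(0, 60) > 0.5, 0:59)
  expect_equal(nrow(none), 0)
  iv <- seizgraph:::runs_to_intervals(c(rep(FALSE, 10), rep(TRUE, 5),
                                        rep(FALSE, 45)), 0:59)
  expect_equal(unname(iv[1, ]), c(10, 15))
})

test_that("whole-recording inference localizes a synthetic seizure", {
  recs <- lapply(1:6, function(i)
    simulate_recording(sim_config(240, n_channels = 4,
                                  seizure_intervals = rbind(c(90, 150)),
                                  seed = 30 + i)))
  fm <- bind_feature_matrices(lapply(recs, function(r)
    window_features(segment_windows(r))))
  fit <- seizure_gcn(fm, head = "brf",
                     config = train_config(epochs = 15, seed = 6,
                                           batch_size = 32))
  new_rec <- simulate_recording(sim_config(240, n_channels = 4,
                                           seizure_intervals = rbind(c(90, 150)),
                                           seed = 99))
  res <- classify_recording(fit, new_rec)
  expect_equal(nrow(res$track), 240)
  expect_true(nrow(res$intervals) >= 1)
  # intersection-over-union with the true (90,150) interval
  secs <- res$track$second
  pred_on <- !is.na(res$track$probability) & res$track$probability > 0.5
  true_on <- secs >= 90 & secs < 150
  iou <- sum(pred_on & true_on) / sum(pred_on | true_on)
  expect_gt(iou, 0.3)

  short <- simulate_recording(sim_config(20, n_channels = 4, seed = 1))
  expect_error(classify_recording(fit, short),
               class = "seizgraph_empty_result_error")
})

test_that("predict() dispatches on recordings, feature matrices and raw rows", {
  fm <- toy_feature_matrix(n = 60, seed = 26)
  fit <- seizure_gcn(fm, head = "brf",
                     config = train_config(epochs = 5, seed = 7,
                                           batch_size = 32))
  p1 <- predict(fit, fm$X[1:4, ])
  expect_length(p1, 4)
  expect_true(all(p1 >= 0 & p1 <= 1))
  cls <- predict(fit, fm, type = "class")
  expect_true(all(cls %in% 0:1))
  expect_error(predict(fit, fm$X[1:4, ], type = "intervals"),
               "raw_recording")
})

test_that("checkpoints round-trip the weights through JSON", {
  fm <- toy_feature_matrix(n = 60, seed = 27)
  fit <- seizure_gcn(fm, head = "lstm",
                     config = train_config(epochs = 2, seed = 8,
                                           batch_size = 32))
  p <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(fit, p)
  ck <- load_checkpoint(p)
  expect_equal(ck$gcn_W[[1]], fit$weights$stack$W[[1]], tolerance = 1e-12)
  expect_equal(ck$lstm$Wh, fit$weights$lstm$Wh, tolerance = 1e-12)
  expect_equal(ck$manifest$head, "gcn_lstm")
})
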