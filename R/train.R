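# Training recipe shared by both models: 60/20/20 shuffled split, min-max
# scaling fitted on training rows only, minority oversampling of training
# rows only, transductive graph over all nodes, Adam (lr 1e-3, weight decay
# 5e-4), cross-entropy, minibatches of 64 training-node indices with
# full-graph propagation, early stopping on validation loss (patience 10)
# with best-validation weights restored.

#' Training configuration
#'
#' @param lr Adam learning rate (default 0.001).
#' @param weight_decay L2 weight decay added to gradients (default 5e-4).
#' @param epochs Maximum epochs (default 50).
#' @param batch_size Training-node minibatch size (default 64).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param split Train/validation/test fractions, summing to 1
#'   (default 0.60/0.20/0.20).
#' @param seed Integer seed driving the split, initialization, resampling
#'   and minibatch order.
#' @param resample A [resample_config()] (default SMOTE to full balance).
#' @param threshold Graph distance threshold (default 0.2).
#' @param hidden GCN/LSTM hidden width (default 256).
#' @param embed GCN output embedding width (default 16).
#' @param bias Use GCN per-layer biases (default `TRUE`).
#' @param n_trees Balanced-forest size (default 100).
#' @param final_state_only LSTM head emits only the final step's logits.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 0.001, weight_decay = 5e-4, epochs = 50L,
                         batch_size = 64L, patience = 10L,
                         split = c(0.60, 0.20, 0.20), seed = 1L,
                         resample = resample_config("smote"),
                         threshold = 0.2, hidden = 256L, embed = 16L,
                         bias = TRUE, n_trees = 100L,
                         final_state_only = FALSE) {
  sg_assert(abs(sum(split) - 1) < 1e-8, "split fractions must sum to 1")
  sg_assert(all(split > 0), "split fractions must be positive")
  sg_assert(epochs >= 1L && batch_size >= 1L && patience >= 1L,
            "epochs, batch_size and patience must be positive")
  structure(list(lr = lr, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), split = split,
                 seed = as.integer(seed), resample = resample,
                 threshold = threshold, hidden = as.integer(hidden),
                 embed = as.integer(embed), bias = bias,
                 n_trees = as.integer(n_trees),
                 final_state_only = final_state_only),
            class = "train_config")
}

#' Shuffled train/validation/test split
#'
#' Sizes are `round(split[1] * n)`, `round(split[2] * n)` and the
#' remainder; the shuffle is seeded.
#'
#' @param n Number of samples (>= 5).
#' @param split Length-3 fractions summing to 1.
#' @param seed Integer seed.
#' @return List with disjoint integer vectors `train`, `val`, `test`
#'   covering `1:n`.
#' @export
split_dataset <- function(n, split = c(0.60, 0.20, 0.20), seed = 1L) {
  sg_assert(n >= 5L, "need at least 5 samples to split")
  n_tr <- round(split[1] * n); n_val <- round(split[2] * n)
  n_te <- n - n_tr - n_val
  sg_assert(n_tr >= 1L && n_val >= 1L && n_te >= 1L,
            "split produces an empty partition")
  perm <- with_rng(seed, sample.int(n))
  list(train = sort(perm[seq_len(n_tr)]),
       val = sort(perm[(n_tr + 1L):(n_tr + n_val)]),
       test = sort(perm[(n_tr + n_val + 1L):n]))
}

# Mean cross-entropy over `idx` rows of logits + gradient (zero elsewhere).
softmax_ce <- function(logits, y, idx) {
  lg <- logits[idx, , drop = FALSE]
  m <- pmax(lg[, 1], lg[, 2])
  lse <- m + log(exp(lg[, 1] - m) + exp(lg[, 2] - m))
  yi <- y[idx]
  picked <- ifelse(yi == 1L, lg[, 2], lg[, 1])
  loss <- mean(lse - picked)
  p1 <- exp(lg[, 2] - lse)
  d <- matrix(0, nrow(logits), 2L)
  d[idx, 1] <- ((1 - p1) - (1 - yi)) / length(idx)
  d[idx, 2] <- (p1 - yi) / length(idx)
  list(loss = loss, dlogits = d)
}

softmax_prob1 <- function(logits) {
  m <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - m); e2 <- exp(logits[, 2] - m)
  e2 / (e1 + e2)
}

# Assemble the transductive node set: scale with a train-fitted scaler,
# oversample training rows, build the graph over real + synthetic nodes.
prepare_nodes <- function(fm, cfg) {
  X <- fm$X; y <- as.integer(fm$y)
  n <- nrow(X)
  idx <- split_dataset(n, cfg$split, cfg$seed)
  sg_assert(length(unique(y[idx$train])) == 2L,
            "training partition must contain both classes")
  sg_assert(length(unique(y[idx$val])) == 2L ||
              length(unique(y[idx$test])) == 2L,
            "evaluation partitions are single-class; enlarge the dataset")
  scaler <- fit_scaler(X[idx$train, , drop = FALSE])
  Xs <- apply_scaler(X, scaler)
  rs_cfg <- cfg$resample
  rs_cfg$seed <- cfg$seed
  rs <- resample_training(Xs[idx$train, , drop = FALSE], y[idx$train], rs_cfg)
  n_syn <- sum(rs$is_synthetic)
  X_nodes <- rbind(Xs, rs$X[rs$is_synthetic, , drop = FALSE])
  y_nodes <- c(y, rs$y[rs$is_synthetic])
  origin <- rep("train", n)
  origin[idx$val] <- "val"; origin[idx$test] <- "test"
  origin <- c(origin, rep("synthetic", n_syn))
  graph <- build_graph(X_nodes, y_nodes, cfg$threshold, origin)
  op <- normalized_adjacency(graph$edges, nrow(X_nodes))
  list(X = X_nodes, y = y_nodes, graph = graph, op = op, scaler = scaler,
       idx = idx, train_nodes = c(idx$train, if (n_syn) n + seq_len(n_syn)),
       n_real = n)
}

# Shared training loop: `forward(params, keep_cache)` returns
# list(logits, caches...); `backward(params, fw, dlogits)` returns grads in
# the same shape as params.  Early stopping on validation loss.
run_training <- function(params, forward, backward, y, train_nodes,
                         val_nodes, cfg) {
  opt <- adam_init(params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_loss = numeric(0),
                        val_acc = numeric(0))
  best <- list(val_loss = Inf, params = params, epoch = 0L)
  stall <- 0L
  with_rng(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(train_nodes)
      nb <- ceiling(length(ord) / cfg$batch_size)
      for (bi in seq_len(nb)) {
        batch <- ord[((bi - 1L) * cfg$batch_size + 1L):
                       min(bi * cfg$batch_size, length(ord))]
        fw <- forward(params, TRUE)
        ce <- softmax_ce(fw$logits, y, batch)
        grads <- backward(params, fw, ce$dlogits)
        st <- adam_step(params, grads, opt, lr = cfg$lr,
                        weight_decay = cfg$weight_decay)
        params <- st$params; opt <- st$state
      }
      fw <- forward(params, FALSE)
      tr <- softmax_ce(fw$logits, y, train_nodes)
      vl <- softmax_ce(fw$logits, y, val_nodes)
      pred <- as.integer(softmax_prob1(fw$logits) > 0.5)
      history[epoch, ] <- list(epoch, tr$loss,
                               mean(pred[train_nodes] == y[train_nodes]),
                               vl$loss,
                               mean(pred[val_nodes] == y[val_nodes]))
      if (vl$loss < best$val_loss - 1e-12) {
        best <- list(val_loss = vl$loss, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
  })
  list(params = best$params, history = history, best_epoch = best$epoch)
}

#' Train the GCN-LSTM seizure classifier
#'
#' Six-layer symmetric-normalized GCN into a single-layer LSTM over the
#' node sequence (window start-time order; synthetic oversampled nodes
#' follow the real sequence) with a per-step linear map to two logits.
#' Trained end-to-end with Adam under cross-entropy on training nodes.
#'
#' @param fm A `feature_matrix` from [window_features()] /
#'   [bind_feature_matrices()].
#' @param cfg A [train_config()].
#' @return A fitted model bundle (class `seizure_gcn`); see [seizure_gcn()].
#' @export
train_gcn_lstm <- function(fm, cfg = train_config()) {
  prep <- prepare_nodes(fm, cfg)
  stack <- gcn_init(ncol(prep$X), cfg$hidden, cfg$embed, cfg$bias, cfg$seed)
  head <- lstm_init(cfg$embed, cfg$hidden, 2L, cfg$seed + 2L)
  params <- list(W = stack$W, b = stack$b, Wx = head$Wx, Wh = head$Wh,
                 hb = head$b, W_out = head$W_out, b_out = head$b_out)

  forward <- function(p, keep_cache) {
    st <- stack; st$W <- p$W; st$b <- p$b
    hd <- head; hd$Wx <- p$Wx; hd$Wh <- p$Wh; hd$b <- p$hb
    hd$W_out <- p$W_out; hd$b_out <- p$b_out
    g <- gcn_forward(st, prep$X, prep$op, keep_cache = keep_cache)
    if (keep_cache) {
      l <- lstm_head_forward(hd, g$H6, keep_cache = TRUE)
      list(logits = l$logits, gcn = g, lstm = l$cache, st = st, hd = hd)
    } else {
      list(logits = lstm_head_forward(hd, g))
    }
  }
  backward <- function(p, fw, dlogits) {
    lb <- lstm_backward(fw$hd, fw$lstm, dlogits)
    gb <- gcn_backward(fw$st, prep$op, fw$gcn$cache, lb$dX)
    list(W = gb$dW, b = gb$db, Wx = lb$dWx, Wh = lb$dWh, hb = lb$db,
         W_out = lb$dW_out, b_out = lb$db_out)
  }

  run <- run_training(params, forward, backward, prep$y, prep$train_nodes,
                      prep$idx$val, cfg)
  p <- run$params
  stack$W <- p$W; stack$b <- p$b
  head$Wx <- p$Wx; head$Wh <- p$Wh; head$b <- p$hb
  head$W_out <- p$W_out; head$b_out <- p$b_out

  H6 <- gcn_forward(stack, prep$X, prep$op)
  logits <- lstm_head_forward(head, H6,
                              final_state_only = cfg$final_state_only)
  score <- softmax_prob1(logits)
  finalize_model(fm, cfg, prep, run, score, "gcn_lstm",
                 list(stack = stack, lstm = head))
}

#' Train the GCN-BRF seizure classifier
#'
#' Stage 1 trains the GCN with a temporary linear softmax map on the 16-d
#' embeddings (same optimization recipe); stage 2 discards that map,
#' extracts embeddings for all nodes from the frozen GCN and fits a
#' balanced random forest on the training-node embeddings.
#'
#' @inheritParams train_gcn_lstm
#' @return A fitted model bundle (class `seizure_gcn`).
#' @export
train_gcn_brf <- function(fm, cfg = train_config()) {
  prep <- prepare_nodes(fm, cfg)
  stack <- gcn_init(ncol(prep$X), cfg$hidden, cfg$embed, cfg$bias, cfg$seed)
  Wc <- with_rng(cfg$seed + 2L, glorot(cfg$embed, 2L))
  params <- list(W = stack$W, b = stack$b, Wc = Wc, bc = numeric(2L))

  forward <- function(p, keep_cache) {
    st <- stack; st$W <- p$W; st$b <- p$b
    g <- gcn_forward(st, prep$X, prep$op, keep_cache = keep_cache)
    H6 <- if (keep_cache) g$H6 else g
    logits <- sweep(H6 %*% p$Wc, 2L, p$bc, "+")
    if (keep_cache) list(logits = logits, gcn = g, H6 = H6, st = st, p = p)
    else list(logits = logits)
  }
  backward <- function(p, fw, dlogits) {
    dH6 <- dlogits %*% t(p$Wc)
    gb <- gcn_backward(fw$st, prep$op, fw$gcn$cache, dH6)
    list(W = gb$dW, b = gb$db, Wc = crossprod(fw$H6, dlogits),
         bc = colSums(dlogits))
  }

  run <- run_training(params, forward, backward, prep$y, prep$train_nodes,
                      prep$idx$val, cfg)
  stack$W <- run$params$W; stack$b <- run$params$b

  H6 <- gcn_forward(stack, prep$X, prep$op)
  forest <- brf_fit(H6[prep$train_nodes, , drop = FALSE],
                    prep$y[prep$train_nodes], n_trees = cfg$n_trees,
                    seed = cfg$seed + 3L)
  score <- brf_predict(forest, H6)$score
  finalize_model(fm, cfg, prep, run, score, "gcn_brf",
                 list(stack = stack, forest = forest))
}

finalize_model <- function(fm, cfg, prep, run, score, head_type, weights) {
  test <- prep$idx$test
  pred <- as.integer(score > 0.5)
  report <- compute_metrics(prep$y[test], pred[test], score[test])
  report$history <- run$history
  structure(list(
    head = head_type, weights = weights, config = cfg,
    scaler = prep$scaler, graph = prep$graph, op = prep$op,
    split = prep$idx, y = prep$y, score = score, report = report,
    history = run$history, best_epoch = run$best_epoch,
    feature_names = fm$feature_names, spec = fm$spec,
    window_s = fm$window_s, overlap_frac = fm$overlap_frac, fs = fm$fs,
    n_real = prep$n_real
  ), class = "seizure_gcn")
}

#' Score new feature rows with a fitted model
#'
#' Rows are scaled with the stored training scaler, attached to the
#' training graph by the distance threshold, propagated through the GCN
#' and scored by the model head.
#'
#' @param model A `seizure_gcn` fit.
#' @param X_new Unscaled feature matrix (same columns as training).
#' @return Numeric vector of ictal probabilities for the new rows.
#' @export
score_new_rows <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  Xs <- apply_scaler(X_new, model$scaler)
  g2 <- attach_new_nodes(model$graph, Xs)
  op2 <- normalized_adjacency(g2$edges, nrow(g2$node_features))
  H6 <- gcn_forward(model$weights$stack, g2$node_features, op2)
  new_idx <- which(g2$node_origin == "new")
  if (model$head == "gcn_lstm") {
    logits <- lstm_head_forward(model$weights$lstm, H6)
    softmax_prob1(logits)[new_idx]
  } else {
    brf_predict(model$weights$forest, H6[new_idx, , drop = FALSE])$score
  }
}

#' Classify a whole recording into a per-second seizure probability track
#'
#' The recording is segmented with the training windowing, featurized and
#' scaled with the stored pipeline state, attached to the training graph
#' and scored; each second's probability is the mean score of all windows
#' covering it (overlapping-chunk averaging), and predicted seizure
#' intervals are maximal runs of probability above `threshold`.
#'
#' @param model A fitted `seizure_gcn`.
#' @param rec A [raw_recording()].
#' @param threshold Decision threshold on the probability track
#'   (default 0.5).
#' @return List with `track` (data frame `second`, `probability`),
#'   `intervals` (matrix of predicted `(start_s, end_s)`), and
#'   `window_scores`.
#' @export
classify_recording <- function(model, rec, threshold = 0.5) {
  sg_assert(inherits(model, "seizure_gcn"), "model must be a seizure_gcn fit")
  ws <- segment_windows(rec, model$window_s, model$overlap_frac)
  fm <- window_features(ws, model$spec %||% feature_spec())
  score <- score_new_rows(model, fm$X)
  agg <- per_second_track(ws$start_times, model$window_s, score,
                          floor(recording_duration(rec)))
  intervals <- runs_to_intervals(agg$probability > threshold, agg$second)
  list(track = agg, intervals = intervals, window_scores = score)
}

# Mean window score per second; a second is covered by a window when it
# lies entirely inside the window span.  Trailing uncovered seconds get NA.
per_second_track <- function(starts, window_s, scores, n_seconds) {
  secs <- seq_len(n_seconds) - 1L
  prob <- vapply(secs, function(s) {
    cover <- starts <= s & (s + 1) <= starts + window_s
    if (any(cover)) mean(scores[cover]) else NA_real_
  }, 0)
  data.frame(second = secs, probability = prob)
}

runs_to_intervals <- function(flag, secs) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  k <- which(r$values)
  if (!length(k)) return(as_interval_matrix(NULL))
  as_interval_matrix(cbind(secs[starts[k]], secs[ends[k]] + 1))
}
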