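#' Fit a graph-based seizure detection model
#'
#' The single modelling front-end: takes the per-window feature matrix of
#' one or more EEG recordings, builds the distance-threshold feature graph
#' and trains the requested classifier head on top of the shared
#' six-layer graph convolutional stack.
#'
#' `head = "lstm"` trains the GCN and an LSTM sequence head end-to-end
#' (per-node logits along the window-time node sequence);
#' `head = "brf"` trains the GCN with a temporary linear softmax map,
#' freezes it, and fits a balanced random forest on the 16-d embeddings.
#'
#' @param features A `feature_matrix` (from [window_features()] or
#'   [bind_feature_matrices()]), or a single [raw_recording()], or a list
#'   of recordings (features are then extracted with defaults).
#' @param head `"lstm"` or `"brf"`.
#' @param config A [train_config()].
#' @param spec A [feature_spec()] used when `features` are raw recordings.
#' @return An object of class `seizure_gcn` with the trained weights, the
#'   frozen scaler and training graph, the data split, per-epoch history
#'   and the held-out test-set [compute_metrics()] report (`$report`).
#' @examples
#' \donttest{
#' cfgs <- lapply(1:4, function(i)
#'   sim_config(120, seizure_intervals = rbind(c(40, 70)), seed = i))
#' recs <- lapply(cfgs, simulate_recording)
#' fm <- bind_feature_matrices(lapply(recs, function(r)
#'   window_features(segment_windows(r))))
#' fit <- seizure_gcn(fm, head = "brf",
#'                    config = train_config(epochs = 5, seed = 1))
#' print(fit)
#' }
#' @export
seizure_gcn <- function(features, head = c("lstm", "brf"),
                        config = train_config(), spec = feature_spec()) {
  head <- match.arg(head)
  if (inherits(features, "raw_recording")) features <- list(features)
  if (is.list(features) && !inherits(features, "feature_matrix") &&
      all(vapply(features, inherits, TRUE, "raw_recording"))) {
    features <- bind_feature_matrices(lapply(features, function(r)
      window_features(segment_windows(r), spec)))
  }
  sg_assert(inherits(features, "feature_matrix"),
            "features must be a feature_matrix or raw recording(s)")
  if (head == "lstm") train_gcn_lstm(features, config)
  else train_gcn_brf(features, config)
}

#' @export
print.seizure_gcn <- function(x, ...) {
  cat(sprintf("<seizure_gcn> head=%s | %d nodes (%d real, %d synthetic), %d edges\n",
              x$head, length(x$y), x$n_real, length(x$y) - x$n_real,
              nrow(x$graph$edges)))
  cat(sprintf("  trained %d epoch(s), best validation at epoch %d\n",
              nrow(x$history), x$best_epoch))
  cat(sprintf("  test: accuracy %.4f | sensitivity %.4f | specificity %.4f | AUC %s\n",
              x$report$accuracy, x$report$sensitivity, x$report$specificity,
              if (is.na(x$report$auc)) "NA" else sprintf("%.4f", x$report$auc)))
  invisible(x)
}

#' @export
summary.seizure_gcn <- function(object, ...) {
  print(object)
  cat("\nTest-set report:\n")
  print(object$report)
  invisible(object$report)
}

#' Predict method for seizure_gcn fits
#'
#' @param object A fitted `seizure_gcn`.
#' @param newdata A [raw_recording()] (whole-recording inference via
#'   [classify_recording()]), a `feature_matrix`, or a plain feature
#'   matrix with training columns.
#' @param type `"prob"` (ictal probability per window), `"class"`
#'   (0/1 at 0.5), or `"intervals"` (per-second track + predicted seizure
#'   intervals; requires a recording).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.seizure_gcn <- function(object, newdata,
                                type = c("prob", "class", "intervals"),
                                ...) {
  type <- match.arg(type)
  if (inherits(newdata, "raw_recording")) {
    res <- classify_recording(object, newdata)
    return(switch(type,
                  intervals = res,
                  prob = res$window_scores,
                  class = as.integer(res$window_scores > 0.5)))
  }
  sg_assert(type != "intervals",
            "interval prediction needs a raw_recording")
  X <- if (inherits(newdata, "feature_matrix")) newdata$X else newdata
  p <- score_new_rows(object, X)
  if (type == "prob") p else as.integer(p > 0.5)
}

#' @export
coef.seizure_gcn <- function(object, ...) {
  w <- list(gcn_W = object$weights$stack$W, gcn_b = object$weights$stack$b)
  if (object$head == "gcn_lstm")
    w <- c(w, object$weights$lstm[c("Wx", "Wh", "b", "W_out", "b_out")])
  w
}

#' Plot method: learning curves, ROC, or the circular graph
#'
#' @param x A fitted `seizure_gcn`.
#' @param which `"learning_curve"`, `"roc"` or `"graph"`.
#' @param ... Passed on to the underlying plot calls.
#' @export
plot.seizure_gcn <- function(x, which = c("learning_curve", "roc", "graph"),
                             ...) {
  which <- match.arg(which)
  if (which == "graph") return(invisible(plot_circular(x$graph, ...)))
  if (which == "roc") {
    sg_assert(!is.null(x$report$roc), "no ROC stored (single-class test set?)")
    graphics::plot(x$report$roc$fpr, x$report$roc$tpr, type = "l",
                   xlab = "False positive rate", ylab = "True positive rate",
                   main = sprintf("ROC (AUC %.4f)", x$report$auc), ...)
    graphics::abline(0, 1, lty = 3)
    return(invisible(x))
  }
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red"),
                    xlab = "Epoch", ylab = "Cross-entropy loss",
                    main = "Learning curve", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' Save / load a fitted model as a JSON-manifest checkpoint
#'
#' Weights are written as named flat arrays in a single JSON archive with a
#' manifest (layer sizes, seed, head type); the balanced forest is refit
#' deterministically from its stored seed and embeddings on load.
#'
#' @param model A `seizure_gcn` fit.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  ser <- function(m) list(dim = dim(as.matrix(m)), x = as.vector(m))
  w <- model$weights
  obj <- list(
    manifest = list(package = "seizgraph",
                    version = as.character(utils::packageVersion("seizgraph")),
                    head = model$head, seed = model$config$seed,
                    dims = w$stack$dims, bias = w$stack$bias),
    gcn_W = lapply(w$stack$W, ser),
    gcn_b = w$stack$b)
  if (model$head == "gcn_lstm")
    obj$lstm <- list(Wx = ser(w$lstm$Wx), Wh = ser(w$lstm$Wh), b = w$lstm$b,
                     W_out = ser(w$lstm$W_out), b_out = w$lstm$b_out)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param path Checkpoint path written by [save_checkpoint()].
#' @return For `load_checkpoint`: list with the manifest and weight arrays.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  de <- function(s) matrix(unlist(s$x), unlist(s$dim)[1], unlist(s$dim)[2])
  num <- function(v) if (is.null(v)) NULL else as.numeric(unlist(v))
  out <- list(manifest = obj$manifest,
              gcn_W = lapply(obj$gcn_W, de),
              gcn_b = lapply(obj$gcn_b, num))
  if (!is.null(obj$lstm))
    out$lstm <- list(Wx = de(obj$lstm$Wx), Wh = de(obj$lstm$Wh),
                     b = num(obj$lstm$b), W_out = de(obj$lstm$W_out),
                     b_out = num(obj$lstm$b_out))
  out
}
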