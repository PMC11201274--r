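# Evaluation metrics for binary ictal/interictal node classification.
# Positive class = ictal (label 1); sensitivity is its recall, specificity
# the recall of the interictal class.

#' Compute the full evaluation report
#'
#' Returns the confusion matrix (rows = truth 0/1, columns = prediction
#' 0/1), accuracy, precision/recall/F1 of the ictal class, sensitivity
#' (= recall), specificity, Cohen's kappa `(p_o - p_e) / (1 - p_e)`, and —
#' when `score` is given and both classes occur — the ROC curve and its
#' trapezoidal AUC over all score thresholds.
#'
#' @param y_true Binary truth vector.
#' @param y_pred Binary predictions.
#' @param score Optional continuous scores in `[0, 1]` (P(ictal)).
#' @return Object of class `eval_report`.
#' @export
compute_metrics <- function(y_true, y_pred, score = NULL) {
  sg_assert(length(y_true) == length(y_pred), "length mismatch")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  cm <- table(factor(y_true, levels = 0:1), factor(y_pred, levels = 0:1))
  cm <- matrix(as.numeric(cm), 2, 2,
               dimnames = list(truth = c("0", "1"), pred = c("0", "1")))
  n <- sum(cm)
  tn <- cm[1, 1]; fp <- cm[1, 2]; fn <- cm[2, 1]; tp <- cm[2, 2]
  acc <- (tp + tn) / n
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  p_o <- acc
  p_e <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 0

  roc <- NULL; auc <- NA_real_
  if (!is.null(score)) {
    sg_assert(length(score) == length(y_true), "score length mismatch")
    if (length(unique(y_true)) < 2L) {
      warning("AUC undefined with a single-class truth vector")
    } else {
      roc <- roc_points(y_true, score)
      auc <- trapezoid_auc(roc)
    }
  }
  structure(list(confusion = cm, accuracy = acc, precision = prec,
                 recall = rec, f1 = f1, sensitivity = rec,
                 specificity = spec, auc = auc, kappa = kappa, roc = roc),
            class = "eval_report")
}

# ROC points over all score thresholds (plus the two endpoints), sorted by
# increasing false-positive rate.
roc_points <- function(y_true, score) {
  # finite sentinel above every score so the curve starts at (0, 0)
  thr <- c(max(score) + 1, sort(unique(score), decreasing = TRUE))
  n_pos <- sum(y_true == 1L); n_neg <- sum(y_true == 0L)
  tpr <- vapply(thr, function(t) sum(score >= t & y_true == 1L) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(score >= t & y_true == 0L) / n_neg, 0)
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

trapezoid_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$confusion)
  cat(sprintf(paste0("accuracy %.4f | precision %.4f | recall/sens %.4f | ",
                     "specificity %.4f\nF1 %.4f | AUC %s | kappa %.4f\n"),
              x$accuracy, x$precision, x$recall, x$specificity, x$f1,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc), x$kappa))
  invisible(x)
}

#' Serialize an evaluation report to JSON (and back)
#'
#' @param report An `eval_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  obj <- list(confusion = unclass(report$confusion),
              accuracy = report$accuracy, precision = report$precision,
              recall = report$recall, f1 = report$f1,
              sensitivity = report$sensitivity,
              specificity = report$specificity,
              auc = report$auc, kappa = report$kappa,
              roc = report$roc, history = report$history)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$confusion <- matrix(as.numeric(obj$confusion), 2, 2,
                          dimnames = list(truth = c("0", "1"),
                                          pred = c("0", "1")))
  if (!is.null(obj$auc) && is.null(obj$auc[[1]])) obj$auc <- NA_real_
  structure(obj, class = "eval_report")
}
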