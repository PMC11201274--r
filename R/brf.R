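# Balanced random forest head on GCN embeddings: each tree is grown on a
# balanced bootstrap (n_min draws with replacement from each class), with
# Gini CART splits and sqrt(d) feature subsampling — realised through
# randomForest's stratified sampling, with the bootstrap balance retained
# (keep.inbag) so it can be verified rather than assumed.

#' Fit a balanced random forest on node embeddings
#'
#' @param embeddings Numeric matrix (`n x d`, typically `n x 16`).
#' @param y Binary labels (0/1), both classes present.
#' @param n_trees Number of trees (default 100).
#' @param mtry Features tried per split (default `floor(sqrt(d))`).
#' @param seed Integer seed.
#' @return Object of class `balanced_forest` wrapping the fitted forest,
#'   its in-bag count matrix and the class levels.
#' @export
brf_fit <- function(embeddings, y, n_trees = 100L, mtry = NULL, seed = 1L) {
  embeddings <- as.matrix(embeddings)
  y <- as.integer(y)
  sg_assert(length(unique(y)) == 2L, "both classes must be present")
  sg_assert(n_trees >= 1L, "n_trees must be >= 1")
  yf <- factor(y, levels = c(0L, 1L))
  n_min <- min(table(yf))
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(embeddings))))
  fit <- with_rng(seed, randomForest::randomForest(
    x = embeddings, y = yf, ntree = n_trees, mtry = mtry,
    strata = yf, sampsize = c(n_min, n_min), replace = TRUE,
    keep.inbag = TRUE, nodesize = 1L))
  structure(list(forest = fit, n_trees = as.integer(n_trees),
                 n_min = as.integer(n_min), y_train = y, seed = seed),
            class = "balanced_forest")
}

#' Predict with a balanced random forest
#'
#' @param forest A `balanced_forest` from [brf_fit()].
#' @param embeddings Numeric matrix of embeddings to score.
#' @return List with `labels` (majority vote, 0/1) and `score` (fraction of
#'   trees voting ictal, usable for ROC analysis).
#' @export
brf_predict <- function(forest, embeddings) {
  if (!inherits(forest, "balanced_forest"))
    sg_stop("forest has not been fitted", "seizgraph_state_error")
  votes <- stats::predict(forest$forest, as.matrix(embeddings),
                          type = "vote", norm.votes = TRUE)
  score <- votes[, "1"]
  list(labels = as.integer(score > 0.5), score = as.numeric(score))
}

#' Per-tree in-bag class counts of a balanced forest
#'
#' @param forest A `balanced_forest`.
#' @return Matrix `n_trees x 2` of bootstrap draw counts per class.
#' @export
brf_inbag_class_counts <- function(forest) {
  inbag <- forest$forest$inbag          # n x n_trees draw counts
  y <- forest$y_train
  t(vapply(seq_len(ncol(inbag)), function(k)
    c(`0` = sum(inbag[y == 0L, k]), `1` = sum(inbag[y == 1L, k])),
    c(`0` = 0, `1` = 0)))
}
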