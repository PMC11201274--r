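# Minority-class oversampling in feature space.  Both samplers operate on
# the TRAINING partition only (the API accepts nothing else) and are
# deterministic under the config seed.

#' Resampling configuration
#'
#' @param method `"none"`, `"smote"` or `"knnor"`.
#' @param k_neighbors Number of minority nearest neighbours (default 5;
#'   auto-clamped to the minority count minus one).
#' @param target_ratio Desired minority/majority ratio after resampling,
#'   in `(0, 1]` (default 1, i.e. full balance).
#' @param lambda_max KNNOR interpolation upper bound in `[0, 1)`
#'   (default 0.5): synthetic points stay closer to their donor.
#' @param safety_quantile KNNOR donor filter: minority points whose
#'   k-th-neighbour distance exceeds this population quantile (default the
#'   median, 0.5) are excluded from the donor pool.
#' @param max_retries Attempt cap per requested KNNOR synthetic point.
#' @param seed Integer seed.
#' @return Object of class `resample_config`.
#' @export
resample_config <- function(method = c("none", "smote", "knnor"),
                            k_neighbors = 5L, target_ratio = 1.0,
                            lambda_max = 0.5, safety_quantile = 0.5,
                            max_retries = 20L, seed = 1L) {
  method <- match.arg(method)
  sg_assert(k_neighbors >= 1L, "k_neighbors must be >= 1")
  sg_assert(target_ratio > 0 && target_ratio <= 1,
            "target_ratio must lie in (0, 1]")
  sg_assert(lambda_max >= 0 && lambda_max < 1, "lambda_max must be in [0, 1)")
  structure(list(method = method, k_neighbors = as.integer(k_neighbors),
                 target_ratio = target_ratio, lambda_max = lambda_max,
                 safety_quantile = safety_quantile,
                 max_retries = as.integer(max_retries),
                 seed = as.integer(seed)),
            class = "resample_config")
}

# exact k-NN indices of each row of A among rows of B (excluding self when
# self_idx gives the row correspondence)
knn_index <- function(A, B, k, self_idx = NULL) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  if (!is.null(self_idx))
    d2[cbind(seq_len(nrow(A)), self_idx)] <- Inf
  res <- apply(d2, 1L, function(r) order(r)[seq_len(k)])
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

prep_resample <- function(X, y, cfg) {
  X <- as.matrix(X); y <- as.integer(y)
  classes <- sort(unique(y))
  sg_assert(length(classes) == 2L, "exactly two classes are required")
  counts <- table(factor(y, levels = classes))
  minority <- classes[which.min(counts)]
  majority <- classes[which.max(counts)]
  n_min <- sum(y == minority); n_maj <- sum(y == majority)
  n_target <- round(cfg$target_ratio * n_maj)
  n_syn <- n_target - n_min
  if (n_syn > 0 && n_min < 2L)
    sg_stop("minority class needs at least 2 samples for oversampling",
            "seizgraph_resampling_error")
  list(X = X, y = y, minority = minority, majority = majority,
       n_min = n_min, n_maj = n_maj, n_syn = max(0L, n_syn),
       k = max(1L, min(cfg$k_neighbors, n_min - 1L)))
}

finish_resample <- function(X, y, X_syn, minority) {
  n_syn <- if (is.null(X_syn)) 0L else nrow(X_syn)
  list(X = rbind(X, X_syn), y = c(y, rep(minority, n_syn)),
       is_synthetic = c(rep(FALSE, length(y)), rep(TRUE, n_syn)))
}

#' SMOTE oversampling of the minority class
#'
#' Each synthetic row is `p + lambda * (q - p)` with `p` a minority row,
#' `q` one of its `k` nearest minority neighbours and
#' `lambda ~ Uniform(0, 1)`.  Original rows are returned unchanged and
#' first; after augmentation the minority count equals
#' `round(target_ratio * majority count)` exactly.
#'
#' @param X_train Numeric matrix of training rows.
#' @param y_train Binary labels.
#' @param cfg A [resample_config()].
#' @return List with `X`, `y`, `is_synthetic`.
#' @export
smote_oversample <- function(X_train, y_train, cfg = resample_config("smote")) {
  p <- prep_resample(X_train, y_train, cfg)
  if (p$n_syn == 0L)
    return(finish_resample(p$X, p$y, NULL, p$minority))
  with_rng(cfg$seed, {
    Xm <- p$X[p$y == p$minority, , drop = FALSE]
    nn <- knn_index(Xm, Xm, p$k, self_idx = seq_len(nrow(Xm)))
    donor <- sample(rep_len(seq_len(nrow(Xm)), p$n_syn))
    pick <- nn[cbind(donor, sample.int(p$k, p$n_syn, replace = TRUE))]
    lam <- stats::runif(p$n_syn)
    X_syn <- Xm[donor, , drop = FALSE] +
      lam * (Xm[pick, , drop = FALSE] - Xm[donor, , drop = FALSE])
    finish_resample(p$X, p$y, X_syn, p$minority)
  })
}

#' KNNOR-style density-aware oversampling
#'
#' Three stages: (i) each minority point is scored by the distance to its
#' k-th nearest minority neighbour, and points scoring above the
#' `safety_quantile` population quantile are removed from the donor pool
#' (sparse outliers make unsafe donors); (ii) candidates are drawn along
#' donor-to-minority-neighbour segments with
#' `lambda ~ Uniform(0, lambda_max)`, `lambda_max < 1`; (iii) a candidate
#' is accepted only if the majority class does not dominate its `k` nearest
#' neighbours in the augmented-so-far population.  Generation retries until
#' the target count or the retry cap; a shortfall returns a partial
#' augmentation with a warning.
#'
#' @inheritParams smote_oversample
#' @return List with `X`, `y`, `is_synthetic`.
#' @export
knnor_oversample <- function(X_train, y_train,
                             cfg = resample_config("knnor")) {
  p <- prep_resample(X_train, y_train, cfg)
  if (p$n_syn == 0L)
    return(finish_resample(p$X, p$y, NULL, p$minority))
  with_rng(cfg$seed, {
    Xm <- p$X[p$y == p$minority, , drop = FALSE]
    nn <- knn_index(Xm, Xm, p$k, self_idx = seq_len(nrow(Xm)))
    kth_dist <- vapply(seq_len(nrow(Xm)), function(i)
      euclidean_distance(Xm[i, ], Xm[nn[i, p$k], ]), 0)
    safe <- which(kth_dist <= stats::quantile(kth_dist, cfg$safety_quantile))
    if (!length(safe)) safe <- seq_len(nrow(Xm))

    X_pop <- p$X                 # augmented-so-far population
    y_pop <- p$y
    accepted <- list()
    attempts <- 0L
    cap <- cfg$max_retries * p$n_syn
    while (length(accepted) < p$n_syn && attempts < cap) {
      attempts <- attempts + 1L
      d <- safe[sample.int(length(safe), 1L)]
      q <- nn[d, sample.int(p$k, 1L)]
      lam <- stats::runif(1L, 0, cfg$lambda_max)
      cand <- Xm[d, ] + lam * (Xm[q, ] - Xm[d, ])
      # neighbourhood vote in the full augmented-so-far population
      dist2 <- colSums((t(X_pop) - cand)^2)
      kk <- min(cfg$k_neighbors, length(dist2))
      vote <- y_pop[order(dist2)[seq_len(kk)]]
      if (sum(vote == p$majority) <= kk / 2) {
        accepted[[length(accepted) + 1L]] <- cand
        X_pop <- rbind(X_pop, cand)
        y_pop <- c(y_pop, p$minority)
      }
    }
    if (length(accepted) < p$n_syn)
      warning(sprintf(
        "KNNOR retry cap reached: %d of %d synthetic points generated",
        length(accepted), p$n_syn))
    X_syn <- if (length(accepted)) do.call(rbind, accepted)
    finish_resample(p$X, p$y, X_syn, p$minority)
  })
}

#' Dispatch oversampling according to a resample_config
#'
#' @inheritParams smote_oversample
#' @return List with `X`, `y`, `is_synthetic`.
#' @export
resample_training <- function(X_train, y_train, cfg) {
  switch(cfg$method,
         none = list(X = as.matrix(X_train), y = as.integer(y_train),
                     is_synthetic = rep(FALSE, length(y_train))),
         smote = smote_oversample(X_train, y_train, cfg),
         knnor = knnor_oversample(X_train, y_train, cfg))
}
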