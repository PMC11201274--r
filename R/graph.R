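# Distance-threshold graph over scaled feature rows: every window is a
# node; an undirected edge links two nodes whose Euclidean distance is
# strictly below the threshold (default 0.2 on min-max-scaled features).
# Node indices are 1-based inside R; on-disk edge lists are written 0-based.

#' Euclidean distance between two feature vectors
#'
#' @param f,g Numeric vectors of equal length.
#' @return Non-negative scalar `sqrt(sum((f - g)^2))`.
#' @export
euclidean_distance <- function(f, g) {
  sg_assert(length(f) == length(g), "vectors must have equal length")
  sqrt(sum((f - g)^2))
}

new_feature_graph <- function(X, edges, labels, threshold, origin) {
  structure(list(node_features = X, edges = edges, labels = labels,
                 threshold = threshold, node_origin = origin),
            class = "feature_graph")
}

#' Build the distance-threshold feature graph
#'
#' One node per row of `X_scaled`; an edge joins rows `i < j` iff their
#' Euclidean distance is strictly less than `threshold`.  Rows are expected
#' to be min-max scaled (see [apply_scaler()]) so the absolute threshold is
#' commensurable; grossly out-of-range values trigger a warning only.
#'
#' @param X_scaled Numeric matrix of scaled feature rows.
#' @param y Binary node labels (1 = ictal).
#' @param threshold Distance threshold (default 0.2).
#' @param origin Optional per-node origin tags (train/val/test/new).
#' @return Object of class `feature_graph` with `edges` as a 2-column
#'   matrix of 1-based index pairs `i < j`.
#' @export
build_graph <- function(X_scaled, y, threshold = 0.2, origin = NULL) {
  X_scaled <- as.matrix(X_scaled)
  sg_assert(threshold > 0, "threshold must be positive")
  sg_assert(nrow(X_scaled) == length(y), "labels must align with rows")
  if (mean(X_scaled < -1 | X_scaled > 2) > 0.05 || max(abs(X_scaled)) > 50)
    warning("feature values far outside [0, 1]; did you forget apply_scaler()?")
  n <- nrow(X_scaled)
  edges <- matrix(integer(0), ncol = 2L)
  if (n >= 2L) {
    d <- as.matrix(stats::dist(X_scaled))
    hit <- which(d < threshold & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit)) edges <- unname(hit[order(hit[, 1], hit[, 2]), ,
                                       drop = FALSE])
  }
  storage.mode(edges) <- "integer"
  new_feature_graph(X_scaled, edges, as.integer(y), threshold,
                    origin %||% rep("train", n))
}

#' @export
print.feature_graph <- function(x, ...) {
  cat(sprintf("<feature_graph> %d nodes (%d ictal), %d edges, threshold %g\n",
              nrow(x$node_features), sum(x$labels), nrow(x$edges),
              x$threshold))
  invisible(x)
}

#' Attach unseen windows to an existing feature graph
#'
#' New rows are appended as nodes with origin `"new"`; edges are added from
#' each new node to every node (existing or new) strictly within the stored
#' threshold.  Existing edges are untouched, so the result equals a full
#' rebuild on the concatenated matrix.
#'
#' @param graph A `feature_graph`.
#' @param X_new_scaled New rows, scaled with the same scaler as the graph.
#' @param y_new Optional labels for the new nodes (default `NA`).
#' @return The augmented `feature_graph`.
#' @export
attach_new_nodes <- function(graph, X_new_scaled, y_new = NULL) {
  sg_assert(inherits(graph, "feature_graph"), "graph must be a feature_graph")
  if (is.null(dim(X_new_scaled))) X_new_scaled <- matrix(X_new_scaled, nrow = 1L)
  sg_assert(ncol(X_new_scaled) == ncol(graph$node_features),
            "feature dimension mismatch with the training graph")
  n_old <- nrow(graph$node_features)
  n_new <- nrow(X_new_scaled)
  X_all <- rbind(graph$node_features, X_new_scaled)
  # distances from new nodes to all nodes
  new_edges <- list()
  for (k in seq_len(n_new)) {
    i <- n_old + k
    d <- sqrt(colSums((t(X_all[seq_len(i - 1L), , drop = FALSE]) -
                         X_all[i, ])^2))
    js <- which(d < graph$threshold)
    if (length(js)) new_edges[[length(new_edges) + 1L]] <- cbind(js, i)
  }
  edges <- rbind(graph$edges,
                 if (length(new_edges)) do.call(rbind, new_edges))
  edges <- unname(as.matrix(edges))
  storage.mode(edges) <- "integer"
  new_feature_graph(
    X_all, edges,
    c(graph$labels, if (is.null(y_new)) rep(NA_integer_, n_new)
      else as.integer(y_new)),
    graph$threshold, c(graph$node_origin, rep("new", n_new)))
}

#' Export a feature graph to GraphML or a tab-separated edge list
#'
#' GraphML (via igraph) carries node attributes `label` and `origin` and the
#' graph attribute `threshold`.  The edge list writes one `i<TAB>j` line per
#' edge using 0-based node indices.
#'
#' @param graph A `feature_graph`.
#' @param path Output file path.
#' @param fmt `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, fmt = c("graphml", "edgelist")) {
  fmt <- tryCatch(match.arg(fmt),
                  error = function(e) sg_stop("unknown export format",
                                              "seizgraph_validation_error"))
  if (fmt == "edgelist") {
    lines <- sprintf("%d\t%d", graph$edges[, 1] - 1L, graph$edges[, 2] - 1L)
    writeLines(lines, path)
  } else {
    g <- as_igraph(graph)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a feature graph to an igraph object
#'
#' @param graph A `feature_graph`.
#' @return An undirected `igraph` graph with `label`/`origin` vertex
#'   attributes and a `threshold` graph attribute.
#' @export
as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = nrow(graph$node_features),
                                directed = FALSE)
  if (nrow(graph$edges))
    g <- igraph::add_edges(g, t(graph$edges))
  igraph::V(g)$label <- graph$labels
  igraph::V(g)$origin <- graph$node_origin
  igraph::graph_attr(g, "threshold") <- graph$threshold
  g
}

#' Read a GraphML file written by [export_graph()]
#'
#' @param path GraphML path.
#' @return A `feature_graph` (without node features).
#' @export
import_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- matrix(as.integer(igraph::as_edgelist(g, names = FALSE)), ncol = 2L)
  el <- if (nrow(el)) t(apply(el, 1L, sort)) else matrix(integer(0), ncol = 2L)
  new_feature_graph(matrix(numeric(0), nrow = igraph::vcount(g)),
                    el, as.integer(igraph::V(g)$label),
                    igraph::graph_attr(g, "threshold"),
                    igraph::V(g)$origin)
}

#' Circular layout of a feature graph
#'
#' Nodes are sorted by class (interictal first), then placed on the unit
#' circle: the k-th node (0-based, post-sort) sits at angle `2*pi*k/n`, so
#' each class occupies a contiguous arc.
#'
#' @param graph A `feature_graph`.
#' @return Data frame with the permutation `node`, `label`, `angle`, `x`,
#'   `y`.
#' @export
circular_layout <- function(graph) {
  n <- nrow(graph$node_features)
  sg_assert(n >= 1L, "graph must have at least one node")
  ord <- order(graph$labels, seq_len(n))
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  data.frame(node = ord, label = graph$labels[ord], angle = ang,
             x = cos(ang), y = sin(ang))
}

#' Draw the circular graph visualization
#'
#' Ictal and interictal nodes are colored differently on the unit circle
#' and edges are drawn as chords.
#'
#' @param graph A `feature_graph`.
#' @param path Optional PNG path; when `NULL`, draws on the active device.
#' @param colors Length-2 vector: interictal, ictal node colors.
#' @return The layout data frame, invisibly.
#' @export
plot_circular <- function(graph, path = NULL,
                          colors = c("#2166AC", "#B2182B")) {
  lay <- circular_layout(graph)
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 800)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(lay$x, lay$y, asp = 1, axes = FALSE, xlab = "", ylab = "",
                 type = "n", main = sprintf(
                   "Feature graph (n=%d, %d edges, threshold %g)",
                   nrow(lay), nrow(graph$edges), graph$threshold))
  pos <- match(seq_len(nrow(lay)), lay$node)   # node -> circle position
  for (e in seq_len(nrow(graph$edges))) {
    i <- pos[graph$edges[e, 1]]; j <- pos[graph$edges[e, 2]]
    graphics::segments(lay$x[i], lay$y[i], lay$x[j], lay$y[j],
                       col = "#00000030")
  }
  node_col <- ifelse(is.na(lay$label), "grey60", colors[lay$label + 1L])
  graphics::points(lay$x, lay$y, pch = 19, cex = 0.9, col = node_col)
  graphics::legend("topright", legend = c("interictal", "ictal"),
                   col = colors, pch = 19, bty = "n")
  invisible(lay)
}
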