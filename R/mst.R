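#' Gower distance on partial correlations
#'
#' Transforms partial-correlation similarities to distances by
#' `d_ij = sqrt(2 (1 - w_ij))` (Gower's similarity-to-distance transform on
#' the signed weights), zero on the diagonal.  Zero-weight pairs receive
#' `d = sqrt(2)`, so the distance graph is complete and a spanning tree
#' always exists; negative partial correlations are farther than absent
#' edges.
#'
#' @param network a `ggm_network` object.
#' @param absolute use `|w|` instead of the signed weights (default FALSE).
#' @return Symmetric p x p distance matrix.
#' @export
gower_distance <- function(network, absolute = FALSE) {
  stopifnot(inherits(network, "ggm_network"))
  w <- network$weights
  if (absolute) w <- abs(w)
  d <- sqrt(2 * (1 - w))
  diag(d) <- 0
  d
}

#' Minimum spanning tree by Kruskal's algorithm
#'
#' Union-find implementation with deterministic tie-breaking: edges are
#' processed in increasing distance order, ties broken by lexicographic
#' node-pair order, so tied instances always yield the same tree.
#'
#' @param distances finite symmetric distance matrix.
#' @param labels optional node labels (defaults to the matrix dimnames).
#' @return An object of class `spanning_tree`: list with `edges` (data
#'   frame: `node_i`, `node_j`, `distance`) and `total_distance`.
#' @export
kruskal_mst <- function(distances, labels = NULL) {
  d <- as.matrix(distances)
  p <- nrow(d)
  if (any(!is.finite(d[upper.tri(d)])))
    stop_ordnet("distances must be finite")
  if (max(abs(d - t(d))) > 1e-10) stop_ordnet("distances must be symmetric")
  if (is.null(labels)) labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("node", seq_len(p))
  pairs <- upper_pairs(p)
  ord <- order(d[pairs], pairs[, 1], pairs[, 2])
  parent <- seq_len(p)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ei <- integer(p - 1); ej <- integer(p - 1); ed <- numeric(p - 1)
  k <- 0L
  for (e in ord) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      k <- k + 1L
      ei[k] <- i; ej[k] <- j; ed[k] <- d[i, j]
      if (k == p - 1L) break
    }
  }
  edges <- data.frame(node_i = labels[ei], node_j = labels[ej],
                      distance = ed)
  structure(list(edges = edges, total_distance = sum(ed),
                 node_labels = labels, index_i = ei, index_j = ej),
            class = "spanning_tree")
}

#' Minimum-spanning-tree backbone of a network
#'
#' Convenience wrapper: [gower_distance()] followed by [kruskal_mst()],
#' attaching the original partial-correlation weight of each tree edge.
#'
#' @param network a `ggm_network` object.
#' @param absolute passed to [gower_distance()].
#' @return A `spanning_tree` whose `edges` data frame also carries `weight`.
#' @export
mst_backbone <- function(network, absolute = FALSE) {
  tree <- kruskal_mst(gower_distance(network, absolute = absolute),
                      labels = network$node_labels)
  tree$edges$weight <- network$weights[cbind(tree$index_i, tree$index_j)]
  tree
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat("Spanning tree:", nrow(x$edges), "edges, total distance",
      format(round(x$total_distance, 4)), "\n")
  invisible(x)
}

#' Export a spanning tree
#'
#' @param tree a `spanning_tree` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree_edges <- function(tree, path) {
  stopifnot(inherits(tree, "spanning_tree"))
  write.csv(tree$edges, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tree_edges
#' @export
write_tree_graphml <- function(tree, path) {
  stopifnot(inherits(tree, "spanning_tree"))
  g <- igraph::graph_from_data_frame(tree$edges, directed = FALSE,
                                     vertices = tree$node_labels)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
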