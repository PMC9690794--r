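#' Node strength centrality
#'
#' Sum of absolute edge weights a node shares with all other nodes.
#'
#' @param network a `ggm_network` object.
#' @return Named vector of per-node strengths.
#' @export
node_strength <- function(network) {
  stopifnot(inherits(network, "ggm_network"))
  setNames(rowSums(abs(network$weights)), network$node_labels)
}

#' Eigenvector centrality
#'
#' Leading eigenvector of the absolute weight matrix (the Perron vector of
#' the largest connected component, zero elsewhere), scaled to a maximum of
#' one.  Undefined for an empty network.
#'
#' @param network a `ggm_network` object with at least one nonzero edge.
#' @return Named vector of per-node eigencentralities in `[0, 1]`.
#' @export
eigencentrality <- function(network) {
  stopifnot(inherits(network, "ggm_network"))
  a <- abs(network$weights)
  if (all(a == 0))
    stop_ordnet("eigencentrality is undefined for an empty network")
  g <- network_igraph(network)
  comp <- igraph::components(g)
  big <- which.max(tabulate(comp$membership))
  keep <- comp$membership == big
  sub <- a[keep, keep, drop = FALSE]
  e <- eigen(sub, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v            # Perron vector: fix sign
  v <- abs(v)                        # guard tiny negative round-off
  out <- numeric(nrow(a))
  out[keep] <- v
  out <- out / max(out)
  setNames(out, network$node_labels)
}

#' Bridge strength centrality
#'
#' Sum of absolute edge weights a node shares with nodes in communities
#' other than its own.
#'
#' @param network a `ggm_network` object.
#' @param communities a `community_assignment` object or an integer/character
#'   vector of per-node community labels (every node must be assigned).
#' @return Named vector of per-node bridge strengths.
#' @export
bridge_strength <- function(network, communities) {
  stopifnot(inherits(network, "ggm_network"))
  lab <- community_labels(communities, nrow(network$weights))
  a <- abs(network$weights)
  cross <- outer(lab, lab, "!=")
  setNames(rowSums(a * cross), network$node_labels)
}

community_labels <- function(communities, p) {
  lab <- if (inherits(communities, "community_assignment"))
    communities$labels else communities
  if (length(lab) != p)
    stop_ordnet("community labels must cover all ", p, " nodes")
  if (anyNA(lab)) stop_ordnet("every node must be assigned a community")
  lab
}

#' Weighted global clustering coefficient
#'
#' Zhang--Horvath clustering on max-normalised absolute weights
#' `wbar = |w| / max |w|`: per node,
#' `C_i = sum_{j != k} wbar_ij wbar_jk wbar_ik / sum_{j != k} wbar_ij wbar_ik`,
#' zero for nodes with fewer than two neighbours; the global value is the
#' mean over nodes with at least two neighbours (0 if there are none).
#' Onnela and Barrat variants are available for sensitivity analyses.
#'
#' @param network a `ggm_network` object.
#' @param method clustering variant, one of `"zhang"` (default), `"onnela"`,
#'   `"barrat"`.
#' @return A scalar in `[0, 1]`.
#' @export
global_clustering <- function(network,
                              method = c("zhang", "onnela", "barrat")) {
  stopifnot(inherits(network, "ggm_network"))
  method <- match.arg(method)
  a <- abs(network$weights)
  if (all(a == 0)) return(0)
  wb <- a / max(a)
  deg <- rowSums(wb > 0)
  ci <- switch(method,
    zhang = {
      num <- diag(wb %*% wb %*% wb)
      den <- rowSums(wb)^2 - rowSums(wb^2)   # sum_{j != k} w_ij w_ik
      ifelse(den > 0, num / den, 0)
    },
    onnela = {
      w3 <- wb^(1 / 3)
      num <- diag(w3 %*% w3 %*% w3)
      k <- rowSums(wb > 0)
      den <- k * (k - 1)
      ifelse(den > 0, num / den, 0)
    },
    barrat = {
      adj <- (wb > 0) + 0
      s <- rowSums(wb)
      k <- rowSums(adj)
      # sum_{j,h} (w_ij + w_ih)/2 a_ij a_jh a_ih
      num <- diag(wb %*% adj %*% adj + adj %*% adj %*% wb) / 2
      den <- s * (k - 1)
      ifelse(den > 0, num / den, 0)
    })
  eligible <- deg >= 2
  if (!any(eligible)) return(0)
  mean(ci[eligible])
}

#' Standardise values to z-scores
#'
#' `(x - mean) / sd` with the sample (n-1) standard deviation, the scaling
#' used for reported centrality tables.
#'
#' @param values numeric vector, length at least 2, with positive spread.
#' @return Vector of z-scores (mean 0, sample SD 1).
#' @export
standardize <- function(values) {
  if (length(values) < 2) stop_ordnet("need at least 2 values")
  s <- sd(values)
  if (s == 0) stop_ordnet("cannot standardise values with zero spread")
  (values - mean(values)) / s
}

#' Centrality table
#'
#' Strength, eigencentrality and bridge strength per node, raw and
#' z-standardised, in the layout of a published centrality table.
#'
#' @param network a `ggm_network` object.
#' @param communities community labels for bridge strength; defaults to
#'   walktrap detection on the network.
#' @return Data frame with one row per node: raw values and `*_z` columns.
#' @export
centrality_table <- function(network, communities = NULL) {
  stopifnot(inherits(network, "ggm_network"))
  if (is.null(communities)) communities <- walktrap_communities(network)
  s <- node_strength(network)
  e <- eigencentrality(network)
  b <- bridge_strength(network, communities)
  data.frame(variable = network$node_labels,
             strength = unname(s), eigencentrality = unname(e),
             bridge_strength = unname(b),
             strength_z = unname(standardize(s)),
             eigencentrality_z = unname(standardize(e)),
             bridge_strength_z = unname(standardize(b)),
             row.names = NULL)
}
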