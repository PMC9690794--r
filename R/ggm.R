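#' Graphical lasso along a penalty path
#'
#' Fits the L1-penalised Gaussian Graphical Model
#' \eqn{\max_K \log\det K - \mathrm{tr}(RK) - \lambda \sum_{i \ne j} |K_{ij}|}
#' (diagonal unpenalised) at each penalty by block coordinate descent with
#' warm starts along the decreasing path.
#'
#' @param R correlation matrix (a `polychoric_matrix` or a plain symmetric
#'   matrix with unit diagonal), positive definite.
#' @param lambdas strictly decreasing vector of positive penalties.
#' @param maxit,tol outer-loop iteration cap and convergence tolerance
#'   (relative to the mean absolute off-diagonal of `R`).
#' @return A list of precision matrices, one per penalty, with attributes
#'   `lambdas`, `iterations` and `converged`.
#' @export
glasso_path <- function(R, lambdas, maxit = 200L, tol = 1e-4) {
  S <- correlation_values(R)
  if (any(lambdas <= 0)) stop_ordnet("penalties must be positive")
  if (length(lambdas) > 1 && any(diff(lambdas) >= 0))
    stop_ordnet("'lambdas' must be strictly decreasing")
  fit <- glasso_path_cpp(S, lambdas, maxit = maxit, tol = tol)
  if (!all(fit$converged)) {
    bad <- which(!fit$converged)[1]
    stop_ordnet("graphical lasso did not converge at lambda = ",
                format(lambdas[bad]), " after ", fit$iterations[bad],
                " iterations")
  }
  Ks <- fit$K
  for (i in seq_along(Ks)) dimnames(Ks[[i]]) <- dimnames(S)
  attr(Ks, "lambdas") <- lambdas
  attr(Ks, "iterations") <- fit$iterations
  attr(Ks, "converged") <- fit$converged
  Ks
}

correlation_values <- function(R) {
  if (inherits(R, "polychoric_matrix")) return(R$rho)
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || max(abs(R - t(R))) > 1e-8)
    stop_ordnet("'R' must be a symmetric correlation matrix")
  R
}

#' Extended Bayesian Information Criterion of a fitted precision matrix
#'
#' `-n (log det K - tr(RK)) + E log(n) + 4 E gamma log(p)`, where `E` is the
#' number of nonzero upper-triangle off-diagonals.  The likelihood term uses
#' the penalised estimate itself (no refit), the convention of EBIC-selected
#' graphical-lasso software.  `gamma = 0` reduces to the ordinary BIC
#' penalty.
#'
#' @param K precision matrix (positive definite).
#' @param R correlation matrix the model was fitted to.
#' @param n sample size.
#' @param gamma EBIC hyperparameter, `>= 0`.
#' @return The EBIC score (smaller is better).
#' @export
ebic_score <- function(K, R, n, gamma = 0.5) {
  S <- correlation_values(R)
  p <- nrow(K)
  ch <- tryCatch(chol(K), error = function(e)
    stop_ordnet("precision matrix is not positive definite"))
  logdet <- 2 * sum(log(diag(ch)))
  E <- sum(abs(K[upper.tri(K)]) > 1e-8)
  -n * (logdet - sum(S * K)) + E * log(n) + 4 * E * gamma * log(p)
}

#' Estimate the sparse partial-correlation network
#'
#' Runs the graphical lasso over a log-spaced penalty grid from
#' `lambda_max = max |off-diagonal of R|` down to
#' `lambda_max * lambda_min_ratio`, scores every path point with
#' [ebic_score()], and returns the minimiser converted to partial
#' correlations `w_ij = -K_ij / sqrt(K_ii K_jj)`.  Entries below 1e-8 in
#' magnitude are treated as exact zeros.
#'
#' For a `polychoric_matrix` estimated under pairwise deletion the effective
#' sample size defaults to the mean of the off-diagonal complete-pair
#' counts.
#'
#' @param R correlation matrix (`polychoric_matrix` or plain matrix).
#' @param n sample size for the EBIC; required for a plain matrix, defaults
#'   to the mean pairwise n for a `polychoric_matrix`.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda penalty grid size (default 100).
#' @param lambda_min_ratio smallest penalty as a fraction of `lambda_max`
#'   (default 0.01).
#' @return An object of class `ggm_network`: list with `weights` (symmetric
#'   partial-correlation matrix, zero diagonal), `node_labels`,
#'   `lambda_selected`, `gamma`, `n_effective`, and `path` (a data frame of
#'   lambda, edge count and EBIC along the path).
#' @export
select_network <- function(R, n = NULL, gamma = 0.5, n_lambda = 100L,
                           lambda_min_ratio = 0.01) {
  S <- correlation_values(R)
  p <- nrow(S)
  if (is.null(n)) {
    if (!inherits(R, "polychoric_matrix"))
      stop_ordnet("'n' is required when 'R' is a plain matrix")
    n <- mean(R$pairwise_n[upper.tri(R$pairwise_n)])
  }
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax == 0) {
    # independence input: empty network at any penalty
    w <- matrix(0, p, p, dimnames = dimnames(S))
    return(new_ggm_network(w, NA_real_, gamma, n,
                           data.frame(lambda = numeric(0), n_edges = integer(0),
                                      ebic = numeric(0))))
  }
  lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                     length.out = n_lambda))
  Ks <- glasso_path(S, lambdas)
  scores <- vapply(Ks, ebic_score, numeric(1), R = S, n = n, gamma = gamma)
  edges <- vapply(Ks, function(K) sum(abs(K[upper.tri(K)]) > 1e-8), integer(1))
  best <- which.min(scores)
  K <- Ks[[best]]
  w <- precision_to_partial(K)
  w[abs(w) < 1e-8] <- 0
  w <- (w + t(w)) / 2
  dimnames(w) <- dimnames(S)
  new_ggm_network(w, lambdas[best], gamma, n,
                  data.frame(lambda = lambdas, n_edges = edges, ebic = scores))
}

new_ggm_network <- function(weights, lambda, gamma, n, path) {
  if (is.null(rownames(weights)))
    dimnames(weights) <- list(paste0("item", seq_len(nrow(weights))),
                              paste0("item", seq_len(nrow(weights))))
  structure(list(weights = weights, node_labels = rownames(weights),
                 lambda_selected = lambda, gamma = gamma, n_effective = n,
                 path = path),
            class = "ggm_network")
}

#' Build a network object from a weight matrix
#'
#' Convenience constructor for analyses that start from an already-estimated
#' (or hand-specified) partial-correlation matrix.
#'
#' @param weights symmetric matrix with zero diagonal, entries in `(-1, 1)`.
#' @param node_labels optional node names.
#' @return A `ggm_network` object.
#' @export
ggm_network <- function(weights, node_labels = NULL) {
  weights <- as.matrix(weights)
  if (max(abs(weights - t(weights))) > 1e-10)
    stop_ordnet("'weights' must be symmetric")
  if (any(diag(weights) != 0)) stop_ordnet("diagonal must be zero")
  if (any(abs(weights) >= 1)) stop_ordnet("|weights| must be < 1")
  if (!is.null(node_labels))
    dimnames(weights) <- list(node_labels, node_labels)
  new_ggm_network(weights, NA_real_, NA_real_, NA_real_,
                  data.frame(lambda = numeric(0), n_edges = integer(0),
                             ebic = numeric(0)))
}

#' @export
print.ggm_network <- function(x, ...) {
  p <- nrow(x$weights)
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("GGM network:", p, "nodes,", ne, "edges (density",
      format(round(edge_density(x), 3)), ")")
  if (!is.na(x$lambda_selected))
    cat("; lambda =", format(signif(x$lambda_selected, 4)),
        "(EBIC gamma =", paste0(format(x$gamma), ")"))
  cat("\n")
  invisible(x)
}

#' Edge density of a network
#'
#' Number of nonzero edges divided by the number of possible edges
#' `p(p-1)/2`.
#'
#' @param network a `ggm_network` object.
#' @return A fraction in `[0, 1]`.
#' @export
edge_density <- function(network) {
  stopifnot(inherits(network, "ggm_network"))
  p <- nrow(network$weights)
  if (p < 2) stop_ordnet("need at least 2 nodes")
  sum(network$weights[upper.tri(network$weights)] != 0) / (p * (p - 1) / 2)
}

#' Export a network as an edge list or GraphML
#'
#' @param network a `ggm_network` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(network, path) {
  el <- network_edge_list(network)
  write.csv(el, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_edges
#' @export
write_network_graphml <- function(network, path) {
  g <- network_igraph(network, signed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

network_edge_list <- function(network) {
  w <- network$weights
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  data.frame(node_i = network$node_labels[idx[, 1]],
             node_j = network$node_labels[idx[, 2]],
             weight = w[idx])
}

# igraph view of the network; absolute weights by default (the convention
# for walktrap / centrality on signed psychological networks)
network_igraph <- function(network, signed = FALSE) {
  w <- network$weights
  a <- if (signed) w else abs(w)
  igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}
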