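#' Walktrap community detection
#'
#' Runs the Pons--Latapy walktrap algorithm on the absolute weight matrix:
#' short random walks define a vertex distance, communities are merged
#' agglomeratively, and the partition is cut at maximum weighted Newman
#' modularity.  Isolated nodes become singleton communities and disconnected
#' components are handled independently; an empty network yields `p`
#' singletons.
#'
#' @param network a `ggm_network` object.
#' @param steps random-walk length (default 4).
#' @return An object of class `community_assignment`: list with `labels`
#'   (integer community id per node, contiguous from 1 in order of first
#'   appearance), `n_communities`, and weighted `modularity` (0 for an
#'   empty network).
#' @export
walktrap_communities <- function(network, steps = 4L) {
  stopifnot(inherits(network, "ggm_network"))
  if (steps < 1) stop_ordnet("'steps' must be >= 1")
  p <- nrow(network$weights)
  g <- network_igraph(network)
  if (igraph::ecount(g) == 0) {
    return(new_community_assignment(seq_len(p), 0, network$node_labels))
  }
  wt <- igraph::cluster_walktrap(g, weights = igraph::E(g)$weight,
                                 steps = steps)
  memb <- as.integer(igraph::membership(wt))
  memb <- match(memb, unique(memb))   # contiguous ids, first-appearance order
  q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
  new_community_assignment(memb, q, network$node_labels)
}

new_community_assignment <- function(labels, modularity, node_labels) {
  structure(list(labels = setNames(as.integer(labels), node_labels),
                 n_communities = length(unique(labels)),
                 modularity = modularity),
            class = "community_assignment")
}

#' @export
print.community_assignment <- function(x, ...) {
  cat("Community assignment:", x$n_communities, "communities; modularity",
      format(round(x$modularity, 4)), "\n")
  invisible(x)
}

#' Weighted Newman modularity of a partition
#'
#' Direct recomputation of `Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m)
#' delta(c_i, c_j)` on the absolute weight matrix, used to verify the value
#' reported by [walktrap_communities()].
#'
#' @param network a `ggm_network` object.
#' @param communities community labels.
#' @return Modularity value (0 for an empty network).
#' @export
modularity_weighted <- function(network, communities) {
  stopifnot(inherits(network, "ggm_network"))
  lab <- community_labels(communities, nrow(network$weights))
  a <- abs(network$weights)
  m2 <- sum(a)
  if (m2 == 0) return(0)
  k <- rowSums(a)
  same <- outer(lab, lab, "==")
  sum((a - outer(k, k) / m2) * same) / m2
}

#' Parametric bootstrap for the number of communities
#'
#' Reconstructs the correlation matrix implied by the estimated network
#' (precision with unit diagonal and off-diagonals `-w_ij`, inverted and
#' rescaled), then repeatedly: samples `n` latent Gaussian vectors,
#' discretises them with the supplied thresholds, re-runs the full
#' estimation pipeline (polychoric matrix, EBIC-glasso, walktrap), and
#' records the number of communities.  Replicates whose estimation fails are
#' skipped; more than 5\% failures is an error.
#'
#' Two 95\% intervals are reported: the percentile interval of the counts,
#' and a normal-approximation interval around the mean count
#' (`mean +/- 1.96 sd / sqrt(n_boot)`).  On integer counts the percentile
#' interval is wide by construction; the normal interval reflects the
#' precision of the average count.
#'
#' @param network a `ggm_network` from [select_network()].
#' @param thresholds per-item latent cut-points (vector recycled to all
#'   items, or list of per-item vectors).
#' @param n sample size per replicate (`>= 50`).
#' @param n_boot number of bootstrap replicates (default 2500).
#' @param seed integer master seed.
#' @param steps walktrap random-walk length.
#' @param gamma,n_lambda,lambda_min_ratio estimation settings passed to
#'   [select_network()].
#' @return An object of class `community_bootstrap`: list with `counts`,
#'   `median`, `ci_low`, `ci_high` (percentile), `mean`, `mean_ci_low`,
#'   `mean_ci_high` (normal approximation), `n_boot`, `n_failed`.
#' @export
bootstrap_communities <- function(network, thresholds, n, n_boot = 2500L,
                                  seed = 1L, steps = 4L, gamma = 0.5,
                                  n_lambda = 100L, lambda_min_ratio = 0.01) {
  stopifnot(inherits(network, "ggm_network"))
  if (n < 50) stop_ordnet("'n' must be >= 50")
  p <- nrow(network$weights)
  thr <- normalise_thresholds(thresholds, p)
  sigma <- implied_correlation(network)
  ch <- chol(sigma)
  k <- max(vapply(thr, length, integer(1))) + 1L
  counts <- rep(NA_integer_, n_boot)
  for (b in seq_len(n_boot)) {
    set.seed(derive_seed(seed, b))
    z <- matrix(rnorm(n * p), n, p) %*% ch
    vals <- matrix(NA_integer_, n, p)
    for (j in seq_len(p))
      vals[, j] <- findInterval(z[, j], thr[[j]]) + 1L
    counts[b] <- tryCatch({
      dat <- ordinal_data(vals, network$node_labels, k)
      R <- polychoric_matrix(dat)
      net <- select_network(R, gamma = gamma, n_lambda = n_lambda,
                            lambda_min_ratio = lambda_min_ratio)
      walktrap_communities(net, steps = steps)$n_communities
    }, error = function(e) NA_integer_)
  }
  n_failed <- sum(is.na(counts))
  if (n_failed > 0.05 * n_boot)
    stop_ordnet(n_failed, " of ", n_boot,
                " bootstrap replicates failed estimation (> 5%)")
  counts <- counts[!is.na(counts)]
  ci <- unname(quantile(counts, c(0.025, 0.975), type = 7))
  se <- sd(counts) / sqrt(length(counts))
  structure(list(counts = counts, median = median(counts),
                 ci_low = ci[1], ci_high = ci[2],
                 mean = mean(counts),
                 mean_ci_low = mean(counts) - 1.96 * se,
                 mean_ci_high = mean(counts) + 1.96 * se,
                 n_boot = as.integer(n_boot), n_failed = n_failed),
            class = "community_bootstrap")
}

# correlation matrix implied by the partial-correlation weights: precision
# with unit diagonal and off-diagonal -w, inverted, rescaled to unit diag
implied_correlation <- function(network) {
  w <- network$weights
  K <- -w
  diag(K) <- 1
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) K <- repair_pd(K)$mat
  cov2cor(solve(K))
}

#' @export
print.community_bootstrap <- function(x, ...) {
  cat("Community-count bootstrap (", x$n_boot, " replicates): median ",
      x$median, ", 95% percentile CI [", x$ci_low, ", ", x$ci_high,
      "], mean ", format(round(x$mean, 4)), " with 95% CI [",
      format(round(x$mean_ci_low, 4)), ", ",
      format(round(x$mean_ci_high, 4)), "]\n", sep = "")
  invisible(x)
}

#' Root mean squared edge weight within and between communities
#'
#' For every unordered community pair (including each community with
#' itself): `RMSEW = sqrt(mean(w^2))` over all node pairs in the block,
#' zero-weight pairs included, plus the mean and SD of `|w|` over the same
#' pairs for comparability with mean/SD summaries.
#'
#' @param network a `ggm_network` object.
#' @param communities community labels.
#' @return Data frame with one row per block pair: `block_a`, `block_b`,
#'   `n_pairs`, `rmsew`, `mean_abs`, `sd_abs`.
#' @export
rmsew <- function(network, communities) {
  stopifnot(inherits(network, "ggm_network"))
  lab <- community_labels(communities, nrow(network$weights))
  w <- network$weights
  pairs <- upper_pairs(nrow(w))
  ca <- pmin(lab[pairs[, 1]], lab[pairs[, 2]])
  cb <- pmax(lab[pairs[, 1]], lab[pairs[, 2]])
  wv <- w[pairs]
  blocks <- unique(data.frame(a = ca, b = cb))
  blocks <- blocks[order(blocks$a, blocks$b), ]
  out <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(i) {
    sel <- ca == blocks$a[i] & cb == blocks$b[i]
    v <- wv[sel]
    data.frame(block_a = blocks$a[i], block_b = blocks$b[i],
               n_pairs = sum(sel),
               rmsew = sqrt(mean(v^2)),
               mean_abs = mean(abs(v)),
               sd_abs = if (sum(sel) > 1) sd(abs(v)) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
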