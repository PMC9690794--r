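#' Nonparametric bootstrap of edge weights
#'
#' Resamples respondents with replacement, re-runs the full estimation
#' pipeline (polychoric matrix + EBIC-glasso) on each replicate, and
#' summarises every edge's bootstrap distribution.  Replicates whose
#' estimation fails are skipped; more than 5\% failures is an error.
#'
#' @param data an `ordinal_data` object with at least 50 rows.
#' @param n_boot number of bootstrap replicates (default 2500).
#' @param seed integer master seed.
#' @param gamma,n_lambda,lambda_min_ratio estimation settings passed to
#'   [select_network()].
#' @return An object of class `edge_bootstrap`: list with `edges` (data
#'   frame per node pair: sample estimate, bootstrap mean, percentile 95\%
#'   CI, proportion of replicates in which the edge was nonzero), the
#'   replicate-by-edge `weights` matrix, the fitted sample `network`,
#'   `n_boot` and `n_failed`.
#' @export
bootstrap_edges <- function(data, n_boot = 2500L, seed = 1L, gamma = 0.5,
                            n_lambda = 100L, lambda_min_ratio = 0.01) {
  stopifnot(inherits(data, "ordinal_data"))
  n <- nrow(data$values)
  if (n < 50) stop_ordnet("'data' must have at least 50 rows")
  net <- select_network(polychoric_matrix(data), gamma = gamma,
                        n_lambda = n_lambda,
                        lambda_min_ratio = lambda_min_ratio)
  p <- ncol(data$values)
  pairs <- upper_pairs(p)
  boots <- matrix(NA_real_, n_boot, nrow(pairs))
  for (b in seq_len(n_boot)) {
    set.seed(derive_seed(seed, b))
    rows <- sample.int(n, n, replace = TRUE)
    boots[b, ] <- tryCatch({
      dat <- ordinal_data(data$values[rows, , drop = FALSE],
                          data$item_labels, data$n_categories)
      w <- select_network(polychoric_matrix(dat), gamma = gamma,
                          n_lambda = n_lambda,
                          lambda_min_ratio = lambda_min_ratio)$weights
      w[pairs]
    }, error = function(e) rep(NA_real_, nrow(pairs)))
  }
  failed <- apply(boots, 1, function(r) anyNA(r))
  if (sum(failed) > 0.05 * n_boot)
    stop_ordnet(sum(failed), " of ", n_boot,
                " bootstrap replicates failed estimation (> 5%)")
  boots <- boots[!failed, , drop = FALSE]
  ci <- apply(boots, 2, quantile, probs = c(0.025, 0.975))
  edges <- data.frame(node_i = data$item_labels[pairs[, 1]],
                      node_j = data$item_labels[pairs[, 2]],
                      sample = net$weights[pairs],
                      boot_mean = colMeans(boots),
                      ci_low = ci[1, ], ci_high = ci[2, ],
                      prop_nonzero = colMeans(boots != 0))
  structure(list(edges = edges, weights = boots, network = net,
                 n_boot = as.integer(n_boot), n_failed = sum(failed)),
            class = "edge_bootstrap")
}

#' @export
print.edge_bootstrap <- function(x, ...) {
  cat("Edge-weight bootstrap:", x$n_boot, "replicates (",
      x$n_failed, "failed );",
      sum(x$edges$sample != 0), "sample edges; mean CI width",
      format(round(mean(x$edges$ci_high - x$edges$ci_low), 4)), "\n")
  invisible(x)
}

#' Correlation-stability (CS) coefficient by case-dropping bootstrap
#'
#' For each drop proportion `q` in `drop_grid`, draws subsamples of size
#' `round((1 - q) n)` without replacement, re-estimates the network, and
#' correlates the subsample statistic (edge weights or node strength,
#' restricted to entries nonzero in the original network for edges) with
#' the full-sample statistic.  The CS coefficient is the largest `q` such
#' that at least `prob` of the correlations reach `cor_threshold`
#' (0 if none does).  Values of at least 0.25 are considered acceptable and
#' at least 0.50 preferable.
#'
#' @param data an `ordinal_data` object.
#' @param statistic `"strength"` (node strength) or `"edges"` (edge
#'   weights).
#' @param drop_grid proportions of cases to drop, strictly inside (0, 0.95).
#' @param n_per_level subsamples per proportion (default 250, so the default
#'   15-level grid costs 3750 refits; tests and quick runs should lower it).
#' @param cor_threshold correlation the subsample statistic must reach
#'   (default 0.7).
#' @param prob required fraction of subsamples reaching the threshold
#'   (default 0.95).
#' @param seed integer master seed.
#' @param gamma,n_lambda,lambda_min_ratio estimation settings passed to
#'   [select_network()].
#' @return An object of class `cs_result`: list with `cs`, the per-level
#'   `correlations` matrix (levels x subsamples), `drop_grid`, `statistic`,
#'   `cor_threshold`, `prob`.
#' @export
cs_coefficient <- function(data, statistic = c("strength", "edges"),
                           drop_grid = seq(0.05, 0.75, by = 0.05),
                           n_per_level = 250L, cor_threshold = 0.7,
                           prob = 0.95, seed = 1L, gamma = 0.5,
                           n_lambda = 100L, lambda_min_ratio = 0.01) {
  stopifnot(inherits(data, "ordinal_data"))
  statistic <- match.arg(statistic)
  if (any(drop_grid <= 0) || any(drop_grid >= 0.95))
    stop_ordnet("'drop_grid' proportions must lie in (0, 0.95)")
  if (n_per_level < 2) stop_ordnet("'n_per_level' must be at least 2")
  n <- nrow(data$values)
  drop_grid <- sort(drop_grid)

  net0 <- select_network(polychoric_matrix(data), gamma = gamma,
                         n_lambda = n_lambda,
                         lambda_min_ratio = lambda_min_ratio)
  stat0 <- network_statistic(net0, statistic)
  keep <- if (statistic == "edges") stat0 != 0 else rep(TRUE, length(stat0))
  if (sum(keep) < 3)
    stop_ordnet("original network has too few nonzero entries to correlate")

  corrs <- matrix(NA_real_, length(drop_grid), n_per_level)
  for (li in seq_along(drop_grid)) {
    m <- round((1 - drop_grid[li]) * n)
    if (m < 50)
      stop_ordnet("drop proportion ", drop_grid[li],
                  " leaves fewer than 50 cases")
    for (b in seq_len(n_per_level)) {
      set.seed(derive_seed(seed, li * 100000L + b))
      rows <- sample.int(n, m)
      corrs[li, b] <- tryCatch({
        dat <- ordinal_data(data$values[rows, , drop = FALSE],
                            data$item_labels, data$n_categories)
        net <- select_network(polychoric_matrix(dat), gamma = gamma,
                              n_lambda = n_lambda,
                              lambda_min_ratio = lambda_min_ratio)
        stat <- network_statistic(net, statistic)
        suppressWarnings(cor(stat0[keep], stat[keep]))
      }, error = function(e) NA_real_)
    }
  }
  fail <- sum(is.na(corrs) & !is.nan(corrs))
  if (fail > 0.05 * length(corrs))
    stop_ordnet(fail, " of ", length(corrs),
                " subsample estimations failed (> 5%)")
  corrs[is.nan(corrs)] <- 0  # zero-variance subsample statistic
  cs <- cs_from_correlations(corrs, drop_grid, cor_threshold, prob)
  structure(list(cs = cs, correlations = corrs, drop_grid = drop_grid,
                 statistic = statistic, cor_threshold = cor_threshold,
                 prob = prob),
            class = "cs_result")
}

network_statistic <- function(network, statistic) {
  if (statistic == "strength") node_strength(network)
  else network$weights[upper_pairs(nrow(network$weights))]
}

#' CS coefficient from a precomputed correlation matrix
#'
#' Applies the CS decision rule to per-level subsample correlations, so the
#' coefficient can be re-evaluated at different thresholds without redoing
#' the case-dropping bootstrap.
#'
#' @param correlations matrix of correlations, rows = drop proportions.
#' @param drop_grid drop proportions (row order).
#' @param cor_threshold,prob decision rule as in [cs_coefficient()].
#' @return The CS coefficient: a member of `drop_grid`, or 0.
#' @export
cs_from_correlations <- function(correlations, drop_grid,
                                 cor_threshold = 0.7, prob = 0.95) {
  ok <- apply(correlations >= cor_threshold, 1, mean, na.rm = TRUE) >= prob
  if (!any(ok)) return(0)
  max(drop_grid[ok])
}

#' @export
print.cs_result <- function(x, ...) {
  cat("CS coefficient (", x$statistic, "): ", format(x$cs),
      "  [threshold ", x$cor_threshold, ", prob ", x$prob, "]\n", sep = "")
  invisible(x)
}
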