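#' Generate a ground-truth sparse Gaussian Graphical Model
#'
#' Builds a random positive-definite precision matrix whose nonzero pattern
#' has a planted block (community) structure, together with the implied
#' partial-correlation network.  Edges are placed exactly: the total edge
#' count is `round(density * p(p-1)/2)`, allocated across block pairs
#' proportionally to the number of node pairs each block pair contains, then
#' sampled uniformly without replacement within each block pair.
#'
#' Edge signs follow `block_signs`: by default, edges within every block are
#' positive and, for the default three-block instrument (stress, coping,
#' support), stress--coping and stress--support edges are negative while
#' coping--support edges are positive.  Positive definiteness is guaranteed
#' by a diagonal-dominance repair (each diagonal entry set to the row sum of
#' absolute off-diagonals plus 0.1) followed by re-standardisation to unit
#' diagonal.
#'
#' @param p number of nodes (questionnaire items).
#' @param density target fraction of the `p(p-1)/2` possible edges, in
#'   `[0, 1]`.
#' @param blocks integer vector of block sizes; must sum to `p`.  Default
#'   `c(7, 6, 4)`: 7 perceived-stress, 6 perceived-coping and 4
#'   social-support items.
#' @param weight_range magnitudes of precision off-diagonals before repair,
#'   drawn uniformly from this interval; both endpoints in `(0, 1)`.  Either
#'   a single interval (or value) applied everywhere, or a list with
#'   elements `within` and `between` giving separate magnitude intervals for
#'   within-block and between-block edges — e.g.
#'   `list(within = 0.3, between = 0.05)` for a strongly separated planted
#'   partition.
#' @param block_signs optional square matrix (blocks x blocks) of -1/+1 edge
#'   signs on the partial-correlation scale.  Default: +1 within blocks;
#'   for exactly three blocks the stress/coping/support pattern described
#'   above, otherwise +1 everywhere.
#' @param allocation how the edge budget is distributed across block pairs:
#'   `"proportional"` (default) gives every block pair edges in proportion
#'   to its number of node pairs, so within- and between-block densities are
#'   equal and community structure is carried by edge weights only;
#'   `"within_first"` fills within-block pairs before spending the
#'   remainder on between-block pairs, producing topologically dense
#'   communities like those of real questionnaire subscales.
#' @param thresholds ordinal cut-points on the latent standard-normal scale,
#'   either a numeric vector recycled to every item or a list of per-item
#'   vectors, each strictly increasing of length `K - 1`.  Default
#'   `c(-1.5, -0.5, 0.5, 1.5)` (five symmetric categories).
#' @param seed integer seed; generation is fully reproducible.
#' @return An object of class `true_ggm`: list with elements `precision`,
#'   `partial_corr`, `communities` (integer block label per node),
#'   `thresholds` (list of per-item cut-points), `item_labels`, and `seed`.
#' @export
generate_true_ggm <- function(p, density, blocks = c(7, 6, 4),
                              weight_range = c(0.1, 0.4),
                              block_signs = NULL,
                              allocation = c("proportional", "within_first"),
                              thresholds = c(-1.5, -0.5, 0.5, 1.5),
                              seed = 1L) {
  allocation <- match.arg(allocation)
  if (length(p) != 1L || p < 3) stop_ordnet("'p' must be a single value >= 3")
  if (density < 0 || density > 1)
    stop_ordnet("'density' must be in [0, 1], got ", density)
  if (sum(blocks) != p)
    stop_ordnet("block sizes must sum to p: sum(", paste(blocks, collapse = ","),
                ") != ", p)
  wr <- if (is.list(weight_range)) {
    if (!all(c("within", "between") %in% names(weight_range)))
      stop_ordnet("list 'weight_range' needs elements 'within' and 'between'")
    list(within = range(weight_range$within),
         between = range(weight_range$between))
  } else {
    list(within = range(weight_range), between = range(weight_range))
  }
  if (any(unlist(wr) <= 0) || any(unlist(wr) >= 1))
    stop_ordnet("'weight_range' magnitudes must lie in (0, 1)")
  nb <- length(blocks)
  if (is.null(block_signs)) {
    block_signs <- matrix(1, nb, nb)
    if (nb == 3L) {
      # stress <-> coping and stress <-> support negative, coping <-> support
      # positive: the sign pattern of the three-community instrument
      block_signs[1, 2] <- block_signs[2, 1] <- -1
      block_signs[1, 3] <- block_signs[3, 1] <- -1
    }
  }
  if (!all(dim(block_signs) == nb))
    stop_ordnet("'block_signs' must be a ", nb, " x ", nb, " matrix")

  community <- rep(seq_len(nb), times = blocks)
  n_pairs <- p * (p - 1) / 2
  m_target <- round(density * n_pairs)

  # enumerate node pairs per block pair
  pairs <- upper_pairs(p)
  stratum <- paste(pmin(community[pairs[, 1]], community[pairs[, 2]]),
                   pmax(community[pairs[, 1]], community[pairs[, 2]]))
  strata <- split(seq_len(nrow(pairs)), stratum)
  sizes <- vapply(strata, length, integer(1))

  if (allocation == "proportional") {
    # proportional allocation with largest-remainder rounding
    raw <- m_target * sizes / n_pairs
    alloc <- floor(raw)
    rem <- m_target - sum(alloc)
    if (rem > 0) {
      ord <- order(raw - alloc, decreasing = TRUE)
      alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
    }
  } else {
    # fill within-block pairs first, then spread the remainder across
    # between-block pairs proportionally
    within <- vapply(strsplit(names(strata), " "),
                     function(s) s[1] == s[2], logical(1))
    alloc <- integer(length(sizes))
    budget <- m_target
    take <- pmin(sizes[within], ceiling(budget * sizes[within] /
                                          max(1, sum(sizes[within]))))
    take <- pmin(sizes[within], take)
    if (sum(take) > budget) {  # trim overshoot deterministically
      over <- sum(take) - budget
      ord <- order(take, decreasing = TRUE)
      for (i in ord) {
        cut <- min(over, take[i]); take[i] <- take[i] - cut; over <- over - cut
        if (over == 0) break
      }
    }
    alloc[within] <- take
    budget <- budget - sum(take)
    if (budget > 0) {
      raw <- budget * sizes[!within] / max(1, sum(sizes[!within]))
      ab <- floor(raw)
      rem <- budget - sum(ab)
      if (rem > 0) {
        ord <- order(raw - ab, decreasing = TRUE)
        ab[ord[seq_len(rem)]] <- ab[ord[seq_len(rem)]] + 1
      }
      alloc[!within] <- ab
    }
  }
  if (any(alloc > sizes))
    stop_ordnet("infeasible density/block configuration: a block pair was ",
                "allocated more edges than it has node pairs")

  set.seed(as.integer(seed))
  chosen <- unlist(lapply(seq_along(strata), function(s) {
    idx <- strata[[s]]
    if (alloc[s] == 0) return(integer(0))
    idx[sample.int(length(idx), alloc[s])]
  }), use.names = FALSE)

  K <- diag(p)
  for (e in chosen) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    sgn <- block_signs[community[i], community[j]]
    rng <- if (community[i] == community[j]) wr$within else wr$between
    mag <- runif(1, rng[1], rng[2])
    # partial correlation carries sign `sgn`; precision entry is its negative
    K[i, j] <- K[j, i] <- -sgn * mag
  }

  # diagonal-dominance repair then standardisation to unit diagonal
  diag(K) <- 0
  diag(K) <- rowSums(abs(K)) + 0.1
  d <- 1 / sqrt(diag(K))
  K <- K * tcrossprod(d)

  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop_ordnet("precision repair failed to reach positive definiteness; ",
                "smallest eigenvalue = ", format(min(ev)))

  pc <- precision_to_partial(K)
  labels <- make_item_labels(blocks)
  thr <- normalise_thresholds(thresholds, p)

  structure(list(precision = K, partial_corr = pc, communities = community,
                 thresholds = thr, item_labels = labels,
                 seed = as.integer(seed)),
            class = "true_ggm")
}

# partial correlations from a precision matrix: standardise and reverse sign
precision_to_partial <- function(K) {
  d <- 1 / sqrt(diag(K))
  pc <- -K * tcrossprod(d)
  diag(pc) <- 0
  pc
}

make_item_labels <- function(blocks) {
  prefix <- if (length(blocks) == 3L) c("stress", "coping", "support")
            else paste0("block", seq_along(blocks))
  unlist(lapply(seq_along(blocks),
                function(b) paste0(prefix[b], seq_len(blocks[b]))),
         use.names = FALSE)
}

normalise_thresholds <- function(thresholds, p) {
  thr <- if (is.list(thresholds)) {
    if (length(thresholds) != p)
      stop_ordnet("threshold list must have one vector per item")
    thresholds
  } else rep(list(as.numeric(thresholds)), p)
  for (t in thr) {
    if (length(t) < 1 || any(diff(t) <= 0))
      stop_ordnet("thresholds must be strictly increasing per item")
  }
  thr
}

#' Study-emulating synthetic dataset
#'
#' Bundles the generator defaults that emulate the motivating survey: a
#' 17-item instrument (7 perceived-stress + 6 perceived-coping + 4
#' social-support items) on a 5-point scale, three planted communities with
#' stronger within-community than between-community partial correlations
#' (within magnitudes 0.2--0.4, between 0.05--0.15 before repair, matching
#' the within/between connectivity contrast reported for such instruments),
#' negative stress--coping and stress--support edges, overall edge density
#' 0.5, n = 367 respondents, and 1.1\% MCAR missingness.
#'
#' @param n number of respondents (default 367).
#' @param density true edge density (default 0.5).
#' @param missing_rate per-cell MCAR missingness (default 0.011).
#' @param seed integer seed.
#' @return A list with elements `model` (the `true_ggm`) and `data` (the
#'   sampled `ordinal_data`).  Within-block node pairs are connected first
#'   (`allocation = "within_first"`), as in real subscales whose items are
#'   densely interconnected.
#' @export
synthetic_study_data <- function(n = 367L, density = 0.5,
                                 missing_rate = 0.011, seed = 1L) {
  model <- generate_true_ggm(17L, density, blocks = c(7, 6, 4),
                             weight_range = list(within = c(0.2, 0.4),
                                                 between = c(0.05, 0.15)),
                             allocation = "within_first", seed = seed)
  data <- sample_ordinal(model, n, seed = derive_seed(seed, 101L))
  if (missing_rate > 0)
    data <- inject_missing(data, missing_rate, seed = derive_seed(seed, 102L))
  list(model = model, data = data)
}

#' Sample ordinal questionnaire data from a true network
#'
#' Draws latent vectors from the zero-mean Gaussian whose covariance is the
#' correlation matrix implied by the model precision, then maps each latent
#' value to the ordinal category whose threshold interval contains it
#' (standard latent-Gaussian discretisation, the data-generating process the
#' polychoric estimator assumes).
#'
#' @param model a `true_ggm` object.
#' @param n number of respondents to draw (`n >= 1`).
#' @param seed integer seed.
#' @return An object of class `ordinal_data`: list with integer matrix
#'   `values` (categories `1..K`, `NA` for missing), `item_labels`, and
#'   `n_categories`.
#' @export
sample_ordinal <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "true_ggm"))
  if (length(n) != 1L || n < 1) stop_ordnet("'n' must be a single value >= 1")
  p <- nrow(model$precision)
  sigma <- solve(model$precision)
  sigma <- cov2cor(sigma)
  ch <- tryCatch(chol(sigma), error = function(e)
    stop_ordnet("model-implied correlation matrix is not positive definite"))
  set.seed(as.integer(seed))
  z <- matrix(rnorm(n * p), n, p) %*% ch
  vals <- matrix(NA_integer_, n, p)
  for (j in seq_len(p))
    vals[, j] <- findInterval(z[, j], model$thresholds[[j]]) + 1L
  k <- max(vapply(model$thresholds, length, integer(1))) + 1L
  ordinal_data(vals, item_labels = model$item_labels, n_categories = k)
}

#' Construct an ordinal dataset object
#'
#' @param values integer matrix of categories in `1..n_categories`, `NA` for
#'   missing cells; at least 3 columns.
#' @param item_labels column labels (defaults to existing colnames or
#'   `item1..itemp`).
#' @param n_categories number of response categories `K`.
#' @return An `ordinal_data` object.
#' @export
ordinal_data <- function(values, item_labels = NULL, n_categories = 5L) {
  values <- as.matrix(values)
  if (ncol(values) < 3) stop_ordnet("need at least 3 items")
  storage.mode(values) <- "integer"
  obs <- values[!is.na(values)]
  if (length(obs) && (min(obs) < 1 || max(obs) > n_categories))
    stop_ordnet("observed categories must lie in 1..", n_categories)
  if (is.null(item_labels))
    item_labels <- colnames(values)
  if (is.null(item_labels))
    item_labels <- paste0("item", seq_len(ncol(values)))
  colnames(values) <- item_labels
  structure(list(values = values, item_labels = item_labels,
                 n_categories = as.integer(n_categories)),
            class = "ordinal_data")
}

#' @export
print.ordinal_data <- function(x, ...) {
  cat("Ordinal dataset:", nrow(x$values), "respondents x",
      ncol(x$values), "items,", x$n_categories, "categories;",
      sum(is.na(x$values)), "missing cells\n")
  invisible(x)
}

#' @export
print.true_ggm <- function(x, ...) {
  p <- nrow(x$precision)
  ne <- sum(x$partial_corr[upper.tri(x$partial_corr)] != 0)
  cat("True GGM:", p, "nodes,", ne, "edges (density",
      format(round(ne / (p * (p - 1) / 2), 3)), "),",
      length(unique(x$communities)), "planted communities\n")
  invisible(x)
}

#' Inject missing values completely at random
#'
#' Each cell is independently set to missing with probability `rate` (MCAR),
#' matching the pairwise-deletion assumption of the estimation pipeline.
#'
#' @param data an `ordinal_data` object.
#' @param rate missingness probability per cell, `0 <= rate < 0.5`.
#' @param seed integer seed.
#' @return The dataset with missing cells added; errors if any item would
#'   lose all its observations.
#' @export
inject_missing <- function(data, rate, seed = 1L) {
  stopifnot(inherits(data, "ordinal_data"))
  if (rate < 0 || rate >= 0.5) stop_ordnet("'rate' must be in [0, 0.5)")
  if (rate == 0) return(data)
  set.seed(as.integer(seed))
  vals <- data$values
  mask <- matrix(runif(length(vals)) < rate, nrow(vals), ncol(vals))
  vals[mask] <- NA_integer_
  all_missing <- colSums(!is.na(vals)) == 0
  if (any(all_missing))
    stop_ordnet("missingness rate ", rate, " left item(s) with no ",
                "observations: ", paste(data$item_labels[all_missing],
                                        collapse = ", "))
  ordinal_data(vals, data$item_labels, data$n_categories)
}

#' Write / read ordinal data as delimited text
#'
#' CSV with a header row; missing cells are written empty.
#'
#' @param data an `ordinal_data` object.
#' @param path file path.
#' @return `write_ordinal_csv` returns `path` invisibly; `read_ordinal_csv`
#'   returns an `ordinal_data` object.
#' @export
write_ordinal_csv <- function(data, path) {
  stopifnot(inherits(data, "ordinal_data"))
  write.csv(as.data.frame(data$values), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ordinal_csv
#' @param n_categories number of response categories; defaults to the
#'   maximum observed value (at least 5).
#' @export
read_ordinal_csv <- function(path, n_categories = NULL) {
  df <- read.csv(path, check.names = FALSE)
  vals <- as.matrix(df)
  if (is.null(n_categories))
    n_categories <- max(5L, max(vals, na.rm = TRUE))
  ordinal_data(vals, item_labels = colnames(df), n_categories = n_categories)
}

#' Export a true network model as plain text
#'
#' Writes the nonzero partial-correlation edges as a CSV edge list
#' (`node_i,node_j,weight`) plus a JSON sidecar holding thresholds,
#' community labels and the generator seed.
#'
#' @param model a `true_ggm` object.
#' @param edge_path CSV path for the edge list.
#' @param json_path path for the JSON sidecar (default: `edge_path` with a
#'   `.json` extension).
#' @return `edge_path`, invisibly.
#' @export
write_true_model <- function(model, edge_path,
                             json_path = sub("\\.csv$", ".json", edge_path)) {
  stopifnot(inherits(model, "true_ggm"))
  pc <- model$partial_corr
  idx <- which(upper.tri(pc) & pc != 0, arr.ind = TRUE)
  el <- data.frame(node_i = model$item_labels[idx[, 1]],
                   node_j = model$item_labels[idx[, 2]],
                   weight = pc[idx])
  write.csv(el, edge_path, row.names = FALSE)
  side <- list(thresholds = model$thresholds,
               communities = as.list(setNames(model$communities,
                                              model$item_labels)),
               seed = model$seed)
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(edge_path)
}
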