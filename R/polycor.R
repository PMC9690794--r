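#' Polychoric correlation of a single item pair
#'
#' Two-step maximum-likelihood estimator of the latent bivariate-normal
#' correlation underlying two ordinal items.  Thresholds are fixed at the
#' standard-normal quantiles of the marginal cumulative proportions (computed
#' after pairwise deletion); the correlation then maximises the bivariate
#' normal likelihood of the two-way contingency table by one-dimensional
#' search on `(-0.999, 0.999)`.  Estimates at the search boundary signal
#' near-duplicate items and are reported with a warning.
#'
#' @param x,y integer vectors of ordinal scores (`NA` allowed); only rows
#'   where both are observed are used, and at least 10 such rows are
#'   required.
#' @param max_categories guard against non-ordinal input (default 12).
#' @return The correlation estimate, a single value in `(-1, 1)`.
#' @export
polychoric_pair <- function(x, y, max_categories = 12L) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 10)
    stop_ordnet("need at least 10 complete pairs, got ", length(x))
  ux <- sort(unique(x)); uy <- sort(unique(y))
  if (length(ux) < 2)
    stop_ordnet("degenerate margin: first item has a single observed category")
  if (length(uy) < 2)
    stop_ordnet("degenerate margin: second item has a single observed category")
  if (length(ux) > max_categories || length(uy) > max_categories)
    stop_ordnet("more than ", max_categories, " categories; not ordinal data?")

  tab <- table(factor(x, levels = ux), factor(y, levels = uy))
  a <- margin_thresholds(rowSums(tab))
  b <- margin_thresholds(colSums(tab))
  fit <- optimize(function(r) polychoric_nll_cpp(unclass(tab), a, b, r),
                  interval = c(-0.999, 0.999), tol = 1e-6)
  rho <- fit$minimum
  if (abs(rho) > 0.9985)
    warning("polychoric estimate at the |rho| = 0.999 search boundary; ",
            "items may be near-duplicates", call. = FALSE)
  rho
}

# thresholds from marginal counts: Phi^-1 of interior cumulative proportions
margin_thresholds <- function(counts) {
  cum <- cumsum(counts) / sum(counts)
  qnorm(cum[-length(cum)])
}

#' Polychoric correlation matrix under pairwise deletion
#'
#' Estimates every item pair with [polychoric_pair()], each on the rows
#' complete for that pair.  Pairwise deletion can yield an indefinite
#' assembly; if so, the matrix is repaired by eigenvalue clipping (negative
#' eigenvalues raised to 1e-6, then rescaled to unit diagonal) and flagged.
#'
#' @param data an `ordinal_data` object.
#' @param min_pairs minimum complete cases per item pair (default 10).
#' @return An object of class `polychoric_matrix`: list with `rho`
#'   (symmetric, unit diagonal), `pairwise_n` (complete-pair counts),
#'   and `repaired` flag.
#' @export
polychoric_matrix <- function(data, min_pairs = 10L) {
  stopifnot(inherits(data, "ordinal_data"))
  vals <- data$values
  p <- ncol(vals)
  rho <- diag(p)
  npair <- matrix(nrow(vals), p, p)
  obs <- !is.na(vals)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      keep <- obs[, i] & obs[, j]
      npair[i, j] <- npair[j, i] <- sum(keep)
      if (sum(keep) < min_pairs)
        stop_ordnet("item pair (", data$item_labels[i], ", ",
                    data$item_labels[j], ") has only ", sum(keep),
                    " complete cases (minimum ", min_pairs, ")")
      r <- tryCatch(polychoric_pair(vals[keep, i], vals[keep, j]),
                    error = function(e)
                      stop_ordnet("item pair (", data$item_labels[i], ", ",
                                  data$item_labels[j], "): ",
                                  conditionMessage(e)))
      rho[i, j] <- rho[j, i] <- r
    }
  }
  diag(npair) <- colSums(obs)
  dimnames(rho) <- dimnames(npair) <- list(data$item_labels, data$item_labels)
  rep_out <- repair_pd(rho)
  structure(list(rho = rep_out$mat, pairwise_n = npair,
                 repaired = rep_out$repaired),
            class = "polychoric_matrix")
}

# Nearest-PD repair by eigenvalue clipping with unit-diagonal rescaling.
# Iterates because the rescaling can nudge the smallest eigenvalue back
# below the floor.
repair_pd <- function(mat, eig_floor = 1e-6, target = 1e-8, max_iter = 10L) {
  repaired <- FALSE
  for (it in seq_len(max_iter)) {
    e <- eigen(mat, symmetric = TRUE)
    if (min(e$values) >= target) break
    repaired <- TRUE
    vals <- pmax(e$values, eig_floor)
    mat <- e$vectors %*% (vals * t(e$vectors))
    mat <- cov2cor(mat)
    mat <- (mat + t(mat)) / 2
  }
  list(mat = mat, repaired = repaired)
}

#' @export
print.polychoric_matrix <- function(x, ...) {
  cat("Polychoric correlation matrix:", nrow(x$rho), "items; pairwise n in [",
      min(x$pairwise_n), ",", max(x$pairwise_n), "];",
      if (x$repaired) "PD-repaired" else "positive definite as assembled",
      "\n")
  invisible(x)
}

#' Export a correlation matrix and its pairwise sample sizes
#'
#' @param R a `polychoric_matrix` object.
#' @param path CSV path for the correlations.
#' @param n_path optional CSV path for the complete-pair counts.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(R, path, n_path = NULL) {
  stopifnot(inherits(R, "polychoric_matrix"))
  write.csv(as.data.frame(R$rho), path, row.names = TRUE)
  if (!is.null(n_path))
    write.csv(as.data.frame(R$pairwise_n), n_path, row.names = TRUE)
  invisible(path)
}
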