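# shared fixtures and small independent oracles

# network from an explicit symmetric weight matrix
net_from_weights <- function(w, labels = NULL) {
  ggm_network(w, node_labels = labels)
}

# symmetric p x p matrix with given upper-triangle entries (column order)
sym_from_upper <- function(p, upper) {
  w <- matrix(0, p, p)
  w[upper.tri(w)] <- upper
  w + t(w)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# all set partitions of 1..n (Bell-number enumeration, small n only)
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  smaller <- all_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(q[[i]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

partition_to_labels <- function(partition, n) {
  lab <- integer(n)
  for (i in seq_along(partition)) lab[partition[[i]]] <- i
  lab
}

# two 4-node cliques (within weight 0.4) joined by a single 0.05 edge
two_clique_weights <- function() {
  w <- matrix(0, 8, 8)
  w[1:4, 1:4] <- 0.4
  w[5:8, 5:8] <- 0.4
  diag(w) <- 0
  w[4, 5] <- w[5, 4] <- 0.05
  w
}

# strongly separated planted 3-block model
strong_model <- function(seed = 1, density = 0.4) {
  generate_true_ggm(17, density,
                    weight_range = list(within = 0.3, between = 0.05),
                    allocation = "within_first", seed = seed)
}

# brute-force bivariate-normal rectangle probability by 1-D quadrature
bvn_rect_prob <- function(lo1, hi1, lo2, hi2, rho) {
  f <- function(x) {
    dnorm(x) * (pnorm((hi2 - rho * x) / sqrt(1 - rho^2)) -
                pnorm((lo2 - rho * x) / sqrt(1 - rho^2)))
  }
  integrate(f, max(lo1, -9), min(hi1, 9), rel.tol = 1e-10)$value
}
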