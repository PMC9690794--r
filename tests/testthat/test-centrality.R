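test_that("strength is the absolute row sum", {
  w <- sym_from_upper(3, c(0.3, -0.2, 0))
  expect_equal(unname(node_strength(net_from_weights(w))), c(0.5, 0.3, 0.2))
  expect_equal(unname(node_strength(net_from_weights(matrix(0, 4, 4)))),
               rep(0, 4))
})

test_that("strengths satisfy the handshake identity", {
  for (s in 1:5) {
    set.seed(s)
    p <- 8
    up <- runif(p * (p - 1) / 2, -0.3, 0.3) * rbinom(p * (p - 1) / 2, 1, 0.5)
    w <- sym_from_upper(p, up)
    expect_equal(sum(node_strength(net_from_weights(w))),
                 2 * sum(abs(up)))
  }
})

test_that("eigencentrality solves the star and equicorrelated cases", {
  # star: hub 1, leaves of equal weight -> hub 1, leaves 1/sqrt(3)
  w <- matrix(0, 4, 4)
  w[1, 2:4] <- w[2:4, 1] <- 0.2
  e <- eigencentrality(net_from_weights(w))
  expect_equal(unname(e), c(1, rep(sqrt(3) / 3, 3)), tolerance = 1e-10)
  # equal off-diagonals: all nodes equivalent
  eq <- matrix(0.15, 5, 5); diag(eq) <- 0
  expect_equal(unname(eigencentrality(net_from_weights(eq))), rep(1, 5))
  # scale invariance
  e2 <- eigencentrality(net_from_weights(2 * w * 0.5 * 2))  # weights doubled
  expect_equal(e2, e)
  expect_error(eigencentrality(net_from_weights(matrix(0, 3, 3))), "empty")
})

test_that("eigencentrality lives on the largest component", {
  w <- matrix(0, 5, 5)
  w[1, 2] <- w[2, 1] <- 0.3
  w[3, 4] <- w[4, 3] <- 0.2
  w[4, 5] <- w[5, 4] <- 0.2
  e <- eigencentrality(net_from_weights(w))
  expect_equal(unname(e[1:2]), c(0, 0))   # smaller component zeroed
  expect_equal(max(e), 1)
  expect_equal(unname(which.max(e)), 4L)
})

test_that("bridge strength sums cross-community weights only", {
  w <- sym_from_upper(3, c(0.3, -0.2, 0))
  b <- bridge_strength(net_from_weights(w), c(1, 1, 2))
  expect_equal(unname(b), c(0.2, 0, 0.2))
  b1 <- bridge_strength(net_from_weights(w), c(1, 1, 1))
  expect_equal(unname(b1), c(0, 0, 0))
  expect_error(bridge_strength(net_from_weights(w), c(1, NA, 2)), "assigned")
  expect_error(bridge_strength(net_from_weights(w), c(1, 2)), "cover")
})

test_that("bridge strength never exceeds strength", {
  for (s in 1:5) {
    set.seed(s + 10)
    p <- 9
    up <- runif(p * (p - 1) / 2, -0.3, 0.3) * rbinom(p * (p - 1) / 2, 1, 0.6)
    net <- net_from_weights(sym_from_upper(p, up))
    comm <- sample(1:3, p, replace = TRUE)
    expect_true(all(bridge_strength(net, comm) <= node_strength(net) + 1e-12))
  }
})

test_that("clustering is 1 on triangles and cliques, 0 on paths", {
  tri <- matrix(0.25, 3, 3); diag(tri) <- 0
  expect_equal(global_clustering(net_from_weights(tri)), 1)
  path <- sym_from_upper(3, c(0.3, 0, 0.4))
  expect_equal(global_clustering(net_from_weights(path)), 0)
  for (v in c(0.05, 0.5)) {
    clique <- matrix(v, 6, 6); diag(clique) <- 0
    expect_equal(global_clustering(net_from_weights(clique)), 1)
  }
})

test_that("clustering variants agree on unweighted-like graphs", {
  w <- two_clique_weights()
  net <- net_from_weights(w)
  z <- global_clustering(net, "zhang")
  o <- global_clustering(net, "onnela")
  b <- global_clustering(net, "barrat")
  for (v in c(z, o, b)) {
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
  expect_gt(z, 0.5)  # two cliques: strongly clustered
})

test_that("standardisation has mean zero, unit sample SD, preserved order", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(3)
  x <- rnorm(17, 2, 5)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_identical(order(z), order(x))
  expect_error(standardize(rep(1, 5)), "zero spread")
  expect_error(standardize(3), "at least 2")
})

test_that("the heaviest node tops the strength z-ranking", {
  m <- strong_model(seed = 30)
  w <- m$partial_corr
  # boost one node's edges so it carries the largest total weight
  w[2, ] <- w[2, ] * 1.9
  w[, 2] <- w[, 2] * 1.9
  w[2, ] <- pmin(pmax(w[2, ], -0.9), 0.9); w[, 2] <- t(w[2, , drop = FALSE])
  net <- net_from_weights(w)
  tab <- centrality_table(net, m$communities)
  expect_equal(which.max(tab$strength_z), 2L)
  expect_equal(tab$strength_z, standardize(tab$strength))
  expect_true(all(tab$bridge_strength <= tab$strength + 1e-12))
})

test_that("centralities are invariant under node relabelling", {
  m <- strong_model(seed = 31)
  net <- net_from_weights(m$partial_corr, labels = m$item_labels)
  perm <- sample(17)
  net2 <- net_from_weights(m$partial_corr[perm, perm],
                           labels = m$item_labels[perm])
  expect_equal(unname(node_strength(net2)), unname(node_strength(net))[perm])
  expect_equal(unname(eigencentrality(net2)),
               unname(eigencentrality(net))[perm], tolerance = 1e-9)
  expect_equal(unname(bridge_strength(net2, m$communities[perm])),
               unname(bridge_strength(net, m$communities))[perm])
  expect_equal(global_clustering(net2), global_clustering(net))
})
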