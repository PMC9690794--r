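test_that("heavy penalty yields the empty network", {
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  K <- glasso_path(R, 10)[[1]]
  expect_true(all(K[upper.tri(K)] == 0))
})

test_that("vanishing penalty recovers closed-form partial correlations", {
  # equicorrelated triple: w = (r - r^2) / (1 - r^2) = 1/3 at r = 0.5
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  K <- glasso_path(R, c(1e-4, 1e-6))[[2]]
  pc <- -K / sqrt(diag(K) %o% diag(K)); diag(pc) <- 0
  expect_lt(max(abs(pc[upper.tri(pc)] - 1 / 3)), 1e-4)
})

test_that("tiny-penalty fits match direct inversion on random matrices", {
  for (s in 1:5) {
    set.seed(s)
    p <- sample(3:6, 1)
    m <- generate_true_ggm(p, 0.5, blocks = p, seed = s)  # well-conditioned
    R <- cov2cor(solve(m$precision))
    K <- glasso_path(R, 1e-6, tol = 1e-7)[[1]]
    pc <- -K / sqrt(diag(K) %o% diag(K)); diag(pc) <- 0
    Ki <- solve(R)
    pci <- -Ki / sqrt(diag(Ki) %o% diag(Ki)); diag(pci) <- 0
    expect_lt(max(abs(pc - pci)), 1e-4)
  }
})

test_that("edge count is non-increasing in the penalty", {
  m <- strong_model(seed = 9)
  d <- sample_ordinal(m, 400, seed = 10)
  R <- polychoric_matrix(d)
  lambdas <- exp(seq(log(0.5), log(0.005), length.out = 30))
  Ks <- glasso_path(R, lambdas)
  counts <- vapply(Ks, function(K) sum(abs(K[upper.tri(K)]) > 1e-8),
                   integer(1))
  # support paths can flicker by a single edge near the zero threshold;
  # the trend as the penalty relaxes must be a clean increase
  expect_true(all(diff(counts) >= -1))
  expect_gt(cor(counts, seq_along(counts), method = "spearman"), 0.95)
  expect_gt(counts[length(counts)], counts[1])
})

test_that("EBIC arithmetic matches the formula", {
  # equal likelihood, E = 10 vs 12, n = 367, p = 17, gamma = 0.5:
  # difference = 2 log(367) + 8 * 0.5 * log(17) = 23.144
  delta <- 2 * log(367) + 8 * 0.5 * log(17)
  K10 <- diag(17); K12 <- diag(17)
  idx10 <- cbind(1:10, c(2:10, 12))   # 10 distinct off-diagonal pairs
  eps <- 1e-4                         # negligible likelihood perturbation
  K10[idx10] <- eps; K10[idx10[, 2:1]] <- eps
  idx12 <- rbind(idx10, cbind(c(13, 15), c(14, 16)))
  K12[idx12] <- eps; K12[idx12[, 2:1]] <- eps
  R <- diag(17)
  d <- ebic_score(K12, R, 367, 0.5) - ebic_score(K10, R, 367, 0.5)
  expect_equal(d, delta, tolerance = 1e-3)
})

test_that("gamma zero reduces EBIC to BIC", {
  K <- diag(4); K[1, 2] <- K[2, 1] <- 0.2
  R <- diag(4)
  loglik_term <- -100 * (log(det(K)) - sum(diag(K)))  # tr(IK) = tr(K)
  expect_equal(ebic_score(K, R, 100, 0), loglik_term + 1 * log(100))
  expect_equal(ebic_score(K, R, 100, 0.5) - ebic_score(K, R, 100, 0),
               4 * 1 * 0.5 * log(4))
})

test_that("diagonal likelihood term matches brute-force evaluation", {
  k <- c(0.5, 1.2, 2, 0.8)
  K <- diag(k)
  R <- diag(4)
  n <- 250
  brute <- -n * sum(log(k) - k)
  expect_equal(ebic_score(K, R, n, 0.5), brute)  # E = 0, no penalty
  expect_error(ebic_score(diag(c(1, -1, 1, 1)), R, n), "positive definite")
})

test_that("identity input selects the empty network", {
  net <- select_network(diag(5), n = 500)
  expect_equal(edge_density(net), 0)
  net2 <- select_network(diag(5), n = 500, gamma = 0)
  expect_equal(edge_density(net2), 0)
})

test_that("network recovery on synthetic data is sparse and sensitive", {
  m <- generate_true_ggm(17, 0.4, seed = 20)
  d <- sample_ordinal(m, 2000, seed = 21)
  net <- select_network(polychoric_matrix(d))
  unpenalised <- sum(solve(cov2cor(solve(m$precision)))[upper.tri(diag(17))] != 0)
  expect_lt(sum(net$weights[upper.tri(net$weights)] != 0), unpenalised)
  expect_gte(edge_sensitivity(m, net), 0.6)
})

test_that("larger gamma never selects a denser model", {
  m <- strong_model(seed = 22)
  d <- sample_ordinal(m, 300, seed = 23)
  R <- polychoric_matrix(d)
  e_heavy <- edge_density(select_network(R, gamma = 0.5))
  e_light <- edge_density(select_network(R, gamma = 0))
  expect_lte(e_heavy, e_light)
})

test_that("permuting items permutes the network identically", {
  m <- strong_model(seed = 24)
  d <- sample_ordinal(m, 500, seed = 25)
  net <- select_network(polychoric_matrix(d))
  perm <- sample(17)
  d2 <- ordinal_data(d$values[, perm], d$item_labels[perm], 5)
  net2 <- select_network(polychoric_matrix(d2))
  expect_lt(max(abs(net2$weights - net$weights[perm, perm])), 1e-4)
  expect_identical(net2$weights == 0, net$weights[perm, perm] == 0)
})

test_that("EBIC minimiser is invariant to duplicated grid points", {
  R <- matrix(0.4, 4, 4); diag(R) <- 1
  lambdas <- exp(seq(log(0.4), log(0.004), length.out = 20))
  Ks <- glasso_path(R, lambdas)
  scores <- vapply(Ks, ebic_score, numeric(1), R = R, n = 300, gamma = 0.5)
  best <- Ks[[which.min(scores)]]
  # duplicate every grid point (strictly decreasing overall, tiny offsets)
  dup <- sort(unique(c(lambdas, lambdas * 0.999)), decreasing = TRUE)
  Ks2 <- glasso_path(R, dup)
  scores2 <- vapply(Ks2, ebic_score, numeric(1), R = R, n = 300, gamma = 0.5)
  best2 <- Ks2[[which.min(scores2)]]
  expect_equal(best2, best, tolerance = 1e-5)
})

test_that("edge density counts nonzero upper-triangle entries", {
  w <- matrix(0, 17, 17)
  pairs <- which(upper.tri(w), arr.ind = TRUE)[1:72, ]
  w[pairs] <- 0.1
  w <- w + t(w)
  net <- net_from_weights(w)
  expect_equal(edge_density(net), 72 / 136)
  expect_equal(edge_density(net_from_weights(matrix(0, 5, 5))), 0)
  full <- matrix(0.1, 5, 5); diag(full) <- 0
  expect_equal(edge_density(net_from_weights(full)), 1)
})

test_that("network exports round-trip the nonzero edges", {
  m <- strong_model(seed = 26)
  net <- net_from_weights(m$partial_corr, labels = m$item_labels)
  path <- tempfile(fileext = ".csv")
  write_network_edges(net, path)
  el <- read.csv(path)
  expect_equal(nrow(el), sum(m$partial_corr[upper.tri(m$partial_corr)] != 0))
  gml <- tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(el))
  unlink(c(path, gml))
})
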