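test_that("identical items estimate at the positive search boundary", {
  x <- rep(1:5, times = c(5, 20, 40, 20, 5))
  expect_warning(r <- polychoric_pair(x, x), "boundary")
  expect_gte(r, 0.99)
})

test_that("simulated latent correlation is recovered", {
  set.seed(42)
  n <- 10000
  z1 <- rnorm(n)
  z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(n)
  cuts <- c(-1.5, -0.5, 0.5, 1.5)
  x <- findInterval(z1, cuts) + 1L
  y <- findInterval(z2, cuts) + 1L
  expect_lt(abs(polychoric_pair(x, y) - 0.5), 0.03)
})

test_that("binary data matches a brute-force tetrachoric grid search", {
  set.seed(7)
  n <- 800
  z1 <- rnorm(n)
  z2 <- -0.4 * z1 + sqrt(1 - 0.16) * rnorm(n)
  x <- as.integer(z1 > 0.3) + 1L
  y <- as.integer(z2 > -0.2) + 1L
  est <- polychoric_pair(x, y)

  # independent oracle: thresholds from margins, likelihood by numeric
  # quadrature, maximiser located on a 1e-3 grid
  a <- qnorm(mean(x == 1))
  b <- qnorm(mean(y == 1))
  tab <- table(x, y)
  grid <- seq(-0.99, 0.99, by = 0.001)
  ll <- vapply(grid, function(r) {
    p11 <- bvn_rect_prob(-Inf, a, -Inf, b, r)
    p12 <- bvn_rect_prob(-Inf, a, b, Inf, r)
    p21 <- bvn_rect_prob(a, Inf, -Inf, b, r)
    p22 <- bvn_rect_prob(a, Inf, b, Inf, r)
    sum(tab * log(pmax(c(p11, p21, p12, p22), 1e-12)))
  }, numeric(1))
  oracle <- grid[which.max(ll)]
  expect_lt(abs(est - oracle), 1e-3 + 1e-6)
})

test_that("estimator is symmetric in its arguments", {
  set.seed(1)
  x <- sample(1:5, 500, replace = TRUE)
  y <- pmin(5, pmax(1, x + sample(-1:1, 500, replace = TRUE)))
  expect_lt(abs(polychoric_pair(x, y) - polychoric_pair(y, x)), 1e-8)
})

test_that("estimate is invariant to monotone relabelling of categories", {
  set.seed(2)
  x <- sample(1:5, 600, replace = TRUE)
  y <- pmin(5, pmax(1, x + sample(-2:2, 600, replace = TRUE)))
  relab <- c(1L, 3L, 4L, 8L, 9L)  # strictly increasing recode
  expect_lt(abs(polychoric_pair(relab[x], relab[y]) -
                polychoric_pair(x, y)), 1e-8)
})

test_that("polychoric corrects the attenuation of discretised Pearson", {
  set.seed(3)
  n <- 10000
  rho <- 0.6
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cuts <- qnorm(c(0.2, 0.4, 0.6, 0.8))  # 5 balanced bins
  x <- findInterval(z1, cuts) + 1L
  y <- findInterval(z2, cuts) + 1L
  pearson <- cor(x, y)
  poly <- polychoric_pair(x, y)
  expect_gt(poly, pearson)
  expect_lt(abs(poly - rho), abs(pearson - rho))
  expect_lt(abs(poly - rho), 0.03)
})

test_that("degenerate margins and short vectors are rejected by name", {
  expect_error(polychoric_pair(rep(2L, 50), rep(1:5, 10)), "single observed")
  expect_error(polychoric_pair(1:5, 1:5), "10 complete pairs")
})

test_that("complete data gives constant pairwise n", {
  m <- generate_true_ggm(3, 0.5, blocks = 3, seed = 1)
  d <- sample_ordinal(m, 200, seed = 2)
  R <- polychoric_matrix(d)
  expect_true(all(R$pairwise_n == 200))
  expect_true(all(diag(R$rho) == 1))
  expect_lt(max(abs(R$rho - t(R$rho))), 1e-12)
})

test_that("pairwise deletion records complete-pair counts", {
  m <- generate_true_ggm(5, 0.3, blocks = 5, seed = 3)
  d <- inject_missing(sample_ordinal(m, 500, seed = 4), 0.05, seed = 5)
  R <- polychoric_matrix(d)
  obs <- !is.na(d$values)
  expect_equal(R$pairwise_n[1, 2], sum(obs[, 1] & obs[, 2]))
  expect_equal(unname(diag(R$pairwise_n)), unname(colSums(obs)))
})

test_that("indefinite assemblies are repaired and flagged", {
  # force a non-PD assembly: r12 = r13 = 0.9 but r23 = -0.9 is infeasible
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  out <- ordnet:::repair_pd(bad)
  expect_true(out$repaired)
  expect_gte(min(eigen(out$mat, symmetric = TRUE)$values), 1e-8)
  expect_equal(diag(out$mat), rep(1, 3))
  # already-PD input passes through untouched
  good <- diag(3)
  out2 <- ordnet:::repair_pd(good)
  expect_false(out2$repaired)
  expect_identical(out2$mat, good)
})

test_that("pairs below the complete-case floor are reported by label", {
  vals <- matrix(sample(1:5, 60, replace = TRUE), 20, 3)
  vals[1:15, 2] <- NA
  d <- ordinal_data(vals, c("a", "b", "c"))
  expect_error(polychoric_matrix(d), "\\(a, b\\)")
})
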