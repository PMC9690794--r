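test_that("zero-density model is an empty network with diagonal precision", {
  m <- generate_true_ggm(5, 0, blocks = 5, seed = 1)
  expect_true(all(m$partial_corr == 0))
  expect_equal(m$precision, diag(5))
})

test_that("edge count hits the density target exactly", {
  m <- generate_true_ggm(17, 0.4, seed = 2)
  ne <- sum(m$partial_corr[upper.tri(m$partial_corr)] != 0)
  expect_equal(ne, round(0.4 * 17 * 16 / 2))  # 54 of 136
  for (d in c(0.1, 0.25, 0.75)) {
    m2 <- generate_true_ggm(17, d, seed = 3)
    ne2 <- sum(m2$partial_corr[upper.tri(m2$partial_corr)] != 0)
    expect_lte(abs(ne2 - d * 136), 1)
  }
})

test_that("cross-block edge signs follow the sign configuration", {
  m <- generate_true_ggm(17, 0.4, seed = 4)
  comm <- m$communities
  pc <- m$partial_corr
  for (i in 1:16) for (j in (i + 1):17) {
    if (pc[i, j] == 0) next
    expected_sign <- if (comm[i] == comm[j]) 1
      else if (comm[i] == 1 || comm[j] == 1) -1  # stress vs coping/support
      else 1                                      # coping vs support
    expect_identical(sign(pc[i, j]), expected_sign)
  }
})

test_that("stored partial correlations match recomputation from precision", {
  for (s in 1:5) {
    m <- generate_true_ggm(10, 0.3, blocks = c(4, 3, 3), seed = s)
    K <- m$precision
    pc <- -K / sqrt(diag(K) %o% diag(K))
    diag(pc) <- 0
    expect_lt(max(abs(pc - m$partial_corr)), 1e-12)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("generation is reproducible and seed-sensitive", {
  a <- generate_true_ggm(17, 0.4, seed = 11)
  b <- generate_true_ggm(17, 0.4, seed = 11)
  c <- generate_true_ggm(17, 0.4, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$partial_corr, c$partial_corr))
})

test_that("infeasible configurations are rejected with parameter errors", {
  expect_error(generate_true_ggm(17, 0.4, blocks = c(7, 6)), "sum")
  expect_error(generate_true_ggm(17, 1.4), "density")
  expect_error(generate_true_ggm(17, 0.4, weight_range = c(0.1, 1.2)),
               "weight_range")
})

test_that("within_first allocation saturates within-block pairs first", {
  m <- strong_model(seed = 5)
  a <- m$partial_corr != 0
  comm <- m$communities
  within_pairs <- sum(outer(comm, comm, "==") & upper.tri(a))
  within_edges <- sum(a[outer(comm, comm, "==") & upper.tri(a)])
  expect_equal(within_edges, min(within_pairs, 54))
})

test_that("ordinal sampling reproduces threshold interval probabilities", {
  m <- generate_true_ggm(5, 0, blocks = 5, seed = 1)
  d <- sample_ordinal(m, 10000, seed = 2)
  freq <- tabulate(d$values, 5) / length(d$values)
  expected <- diff(pnorm(c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf)))
  expect_lt(max(abs(freq - expected)), 0.02)
})

test_that("independence model yields near-zero polychoric correlations", {
  m <- generate_true_ggm(5, 0, blocks = 5, seed = 3)
  d <- sample_ordinal(m, 10000, seed = 4)
  R <- polychoric_matrix(d)
  off <- R$rho[upper.tri(R$rho)]
  expect_lt(max(abs(off)), 0.05)
  expect_false(R$repaired)
})

test_that("large-sample polychorics converge to model-implied correlations", {
  m <- strong_model(seed = 6)
  sigma <- cov2cor(solve(m$precision))
  d <- sample_ordinal(m, 50000, seed = 7)
  R <- polychoric_matrix(d)
  expect_lt(max(abs(R$rho - sigma)), 0.03)
})

test_that("sampling rejects invalid sample sizes", {
  m <- generate_true_ggm(5, 0, blocks = 5, seed = 1)
  expect_error(sample_ordinal(m, 0), "n")
})

test_that("missingness injection is MCAR at the requested rate", {
  m <- generate_true_ggm(17, 0.4, seed = 8)
  d <- sample_ordinal(m, 367, seed = 9)
  expect_identical(inject_missing(d, 0, seed = 1), d)
  d2 <- inject_missing(d, 0.011, seed = 10)
  n_missing <- sum(is.na(d2$values))
  # binomial 99% interval around 367*17*0.011 = 68.6
  bounds <- qbinom(c(0.005, 0.995), 367 * 17, 0.011)
  expect_gte(n_missing, bounds[1])
  expect_lte(n_missing, bounds[2])
  expect_identical(d2$item_labels, d$item_labels)
  # high rate on a tiny matrix either runs or raises the all-missing error
  m3 <- generate_true_ggm(3, 0, blocks = 3, seed = 1)
  d3 <- sample_ordinal(m3, 10, seed = 1)
  res <- tryCatch(inject_missing(d3, 0.4, seed = 2), error = conditionMessage)
  if (is.character(res)) expect_match(res, "no observations")
  else expect_s3_class(res, "ordinal_data")
  expect_error(inject_missing(d, 0.6), "rate")
})

test_that("datasets round-trip through CSV with empty missing cells", {
  m <- generate_true_ggm(5, 0.2, blocks = 5, seed = 11)
  d <- inject_missing(sample_ordinal(m, 60, seed = 12), 0.05, seed = 13)
  path <- tempfile(fileext = ".csv")
  write_ordinal_csv(d, path)
  d2 <- read_ordinal_csv(path)
  expect_identical(d2$values, d$values)
  expect_identical(d2$item_labels, d$item_labels)
  unlink(path)
})

test_that("true models export as edge list plus JSON sidecar", {
  m <- generate_true_ggm(6, 0.4, blocks = c(3, 3), seed = 14)
  ep <- tempfile(fileext = ".csv")
  write_true_model(m, ep)
  el <- read.csv(ep)
  expect_equal(nrow(el), sum(m$partial_corr[upper.tri(m$partial_corr)] != 0))
  side <- jsonlite::read_json(sub("\\.csv$", ".json", ep))
  expect_equal(side$seed, 14)
  expect_length(side$communities, 6)
  unlink(c(ep, sub("\\.csv$", ".json", ep)))
})
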