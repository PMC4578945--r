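test_that("A/B/C components match hand-evaluated min-sums", {
  expect_equal(abc(c(4, 1, 0), c(1, 1, 3)), list(A = 2, B = 3, C = 3))
  same <- abc(c(2, 3), c(2, 3))
  expect_equal(same, list(A = 5, B = 0, C = 0))
  expect_equal(abc(c(5, 2), c(0, 0)), list(A = 0, B = 7, C = 0))
  expect_error(abc(c(1, 2), c(1, 2, 3)), "lengths differ")
})

test_that("percentage difference matches its closed forms and conventions", {
  expect_equal(percentage_difference(c(4, 1, 0), c(1, 1, 3)), 0.6)
  expect_equal(percentage_difference(c(2, 0), c(0, 1)), 1)
  expect_equal(percentage_difference(c(3, 1), c(3, 1)), 0)
  expect_equal(percentage_difference(c(0, 0), c(0, 0)), 0) # both-empty convention
  set.seed(42)
  for (i in 1:50) {
    y1 <- rlnorm(8) * rbinom(8, 1, 0.7)
    y2 <- rlnorm(8) * rbinom(8, 1, 0.7)
    expect_equal(percentage_difference(y1, y2), bray_oracle(y1, y2),
                 tolerance = 1e-12)
  }
})

test_that("pair decomposition is additive and handles empty observations", {
  expect_equal(decompose_pair(c(4, 1, 0), c(1, 1, 3)), list(repl = 0.6, diff = 0))
  expect_equal(decompose_pair(c(2, 0), c(0, 1)), list(repl = 2 / 3, diff = 1 / 3))
  expect_equal(decompose_pair(c(5, 2), c(0, 0)), list(repl = 0, diff = 1))
  expect_equal(decompose_pair(c(0, 0), c(0, 0)), list(repl = 0, diff = 0))
  set.seed(7)
  for (i in 1:200) {
    y1 <- rlnorm(10) * rbinom(10, 1, 0.6)
    y2 <- rlnorm(10) * rbinom(10, 1, 0.6)
    comp <- decompose_pair(y1, y2)
    expect_lt(abs(comp$repl + comp$diff - percentage_difference(y1, y2)), 1e-12)
  }
})

test_that("matrix decomposition reproduces pairwise values and the vegan oracle", {
  dc <- decompose_matrix(toy_matrix())
  expect_equal(dc$D_total["a", "b"], 0.6)
  expect_equal(dc$D_total["a", "c"], 1)
  expect_equal(dc$D_total["b", "c"], 0.25)
  expect_true(isSymmetric(dc$D_total))
  expect_equal(unname(diag(dc$D_total)), rep(0, 3))
  expect_equal(dc$D_total, dc$D_repl + dc$D_diff, tolerance = 1e-12)

  m <- random_table(10, 6, seed = 3)
  dc2 <- decompose_matrix(m)
  oracle <- as.matrix(vegan::vegdist(m, method = "bray"))
  dimnames(oracle) <- dimnames(dc2$D_total)
  expect_equal(dc2$D_total, oracle, tolerance = 1e-12)
})

test_that("dissimilarities are invariant to species order and common scaling", {
  m <- random_table(8, 7, seed = 11)
  dc <- decompose_matrix(m)
  perm <- sample(ncol(m))
  dc_p <- decompose_matrix(m[, perm])
  expect_equal(dc$D_total, dc_p$D_total, tolerance = 1e-12)
  expect_equal(dc$D_repl, dc_p$D_repl, tolerance = 1e-12)
  dc_s <- decompose_matrix(m * 3.7)
  expect_equal(dc$D_total, dc_s$D_total, tolerance = 1e-12)
  expect_equal(dc$D_diff, dc_s$D_diff, tolerance = 1e-12)
})

test_that("square-rooted percentage difference is Euclidean-embeddable", {
  expect_equal(sqrt_embed(matrix(c(0, 0.6, 0.6, 0), 2))[1, 2], sqrt(0.6))
  m <- random_table(15, 8, seed = 5)
  d <- sqrt_embed(decompose_matrix(m)$D_total)
  g <- gower_oracle(d^2)
  expect_gte(min(eigen(g, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("pcoa reconstructs Euclidean distances and satisfies the trace identity", {
  two <- matrix(c(0, sqrt(0.6), sqrt(0.6), 0), 2)
  ord <- pcoa(two)
  expect_equal(ncol(ord$coordinates), 1)
  expect_equal(abs(diff(ord$coordinates[, 1])), sqrt(0.6), tolerance = 1e-10)

  d <- sqrt_embed(decompose_matrix(toy_matrix())$D_total)
  ord2 <- pcoa(d)
  rec <- as.matrix(dist(ord2$coordinates))
  expect_equal(unname(rec), unname(d), tolerance = 1e-10)
  g <- gower_oracle(d^2)
  expect_equal(sum(ord2$eigenvalues), sum(diag(g)), tolerance = 1e-10)

  # against the classical-scaling implementation in base R
  m <- random_table(9, 5, seed = 8)
  de <- as.matrix(dist(m))
  mine <- pcoa(de)$coordinates
  expect_equal(unname(as.matrix(dist(mine))), unname(de), tolerance = 1e-8)

  # a metric-violating input warns and drops axes
  bad <- matrix(c(0, 1, 3, 1, 0, 1, 3, 1, 0), 3)
  expect_warning(pcoa(bad), "not Euclidean")
})
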