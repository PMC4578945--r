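test_that("a clean two-block contrast is split first with R^2 = 1", {
  y <- rbind(matrix(0, 6, 3), matrix(5, 6, 3))
  tree <- mrt_fit(y, data.frame(site = rep(c("a", "b", "c", "d"), each = 3)),
                  n_perm = 99, seed = 1)
  expect_equal(tree$r_squared, 1)
  expect_equal(nrow(tree$splits), 1)
  expect_equal(sort(unique(tree$leaves[1:6])), 1)
  expect_true(all(tree$leaves[1:6] != tree$leaves[7:12]))
})

test_that("homogeneous responses stay a single leaf", {
  set.seed(2)
  y <- matrix(rnorm(20 * 3), 20, 3)
  singles <- replicate(20, {
    yb <- matrix(rnorm(20 * 3), 20, 3)
    tree <- mrt_fit(yb, data.frame(time = rep(1:5, each = 4)),
                    n_perm = 99)
    tree$n_leaves
  })
  expect_gte(mean(singles == 1), 0.8)
})

test_that("ordered and categorical splits agree with an exhaustive SS oracle", {
  set.seed(3)
  y <- matrix(rnorm(18 * 4), 18, 4)
  x <- rep(1:6, each = 3)
  tree <- mrt_fit(y, data.frame(time = x), max_leaves = 2, n_perm = 0)
  # oracle: evaluate every boundary by brute force
  ss_of <- function(sel) {
    a <- y[sel, , drop = FALSE]; b <- y[!sel, , drop = FALSE]
    sum(scale(a, scale = FALSE)^2) + sum(scale(b, scale = FALSE)^2)
  }
  best <- min(sapply(1:5, function(k) ss_of(x <= k + 0.5)))
  got <- sum(sapply(split(seq_len(18), tree$leaves), function(i) {
    sum(scale(y[i, , drop = FALSE], scale = FALSE)^2)
  }))
  expect_equal(got, best, tolerance = 1e-10)

  # categorical: exhaustive partition search finds the planted split {a,c} vs {b,d}
  y2 <- matrix(0, 16, 2)
  g <- rep(c("a", "b", "c", "d"), each = 4)
  y2[g %in% c("a", "c"), ] <- 4
  tree2 <- mrt_fit(y2 + rnorm(32, sd = 0.1), data.frame(site = g),
                   max_leaves = 2, n_perm = 99, seed = 4)
  expect_setequal(unique(tree2$leaves[g %in% c("a", "c")]),
                  setdiff(1:2, unique(tree2$leaves[g %in% c("b", "d")])))
})

test_that("many-level categorical predictors fall back to the ordered heuristic", {
  set.seed(5)
  g <- rep(sprintf("s%02d", 1:17), each = 2)
  y <- matrix(rnorm(34 * 3), 34, 3)
  y[g <= "s08", ] <- y[g <= "s08", ] + 5
  tree <- mrt_fit(y, data.frame(site = g), max_leaves = 2, n_perm = 99, seed = 6)
  expect_true(any(tree$splits$heuristic))
  expect_gt(tree$r_squared, 0.5)
})

test_that("chronological split recovers an abrupt compositional change", {
  set.seed(7)
  times <- rep(c(2007, 2007.5, 2008, 2008.5, 2009, 2009.5), each = 3)
  recov <- replicate(40, {
    y <- matrix(rnorm(18 * 6, sd = 0.8), 18, 6)
    y[times >= 2009, 1:3] <- y[times >= 2009, 1:3] + 3
    cs <- chronological_split(y, times, n_perm = 0)
    cs$boundary
  })
  expect_gte(mean(recov == 2008.75), 0.95)

  # two time points, distinct compositions
  y2 <- rbind(matrix(0, 3, 2), matrix(2, 3, 2))
  cs2 <- chronological_split(y2 + rnorm(12, sd = 1e-8), rep(1:2, each = 3),
                             n_perm = 99, seed = 1)
  expect_equal(cs2$boundary, 1.5)
  expect_equal(cs2$r_squared, 1, tolerance = 1e-10)

  expect_error(chronological_split(y2, rep(1, 6)), "distinct")
})

test_that("constant composition yields a non-significant chronological split", {
  set.seed(8)
  ps <- replicate(20, {
    y <- matrix(rnorm(24 * 4), 24, 4)
    chronological_split(y, rep(1:6, each = 4), n_perm = 99)$p_value
  })
  expect_gte(mean(ps > 0.05), 0.8)
})

test_that("chronological split R^2 equals the RDA R^2 of the induced factor", {
  set.seed(9)
  y <- matrix(rnorm(30 * 5), 30, 5)
  times <- rep(seq(2004, 2008.5, 0.5), each = 3)
  y[times > 2006, ] <- y[times > 2006, ] + 1
  cs <- chronological_split(y, times, n_perm = 0)
  fit <- betashift::rda(y, cs$groups, n_perm = 0)
  expect_equal(cs$r_squared, fit$r_squared, tolerance = 1e-10)

  # a 2-leaf tree on time alone is the same partition
  tree <- mrt_fit(y, data.frame(time = times), max_leaves = 2, n_perm = 0)
  expect_equal(length(unique(paste(tree$leaves, cs$groups))), 2)
})
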