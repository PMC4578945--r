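test_that("RDA R^2 matches vegan and a centroid-projection oracle", {
  set.seed(1)
  y <- matrix(rnorm(60), 20, 3)
  g <- rep(c("a", "b"), each = 10)
  fit <- betashift::rda(y, g, n_perm = 0)
  v <- vegan::rda(y ~ g)
  expect_equal(fit$r_squared, v$CCA$tot.chi / v$tot.chi, tolerance = 1e-10)

  # oracle: replace each row by its group centroid, compare explained SS
  yc <- scale(y, scale = FALSE)
  cent <- apply(yc, 2, function(col) ave(col, g))
  expect_equal(fit$r_squared, sum(cent^2) / sum(yc^2), tolerance = 1e-10)
})

test_that("RDA separates distinct groups and scores carry direction", {
  y <- rbind(matrix(1, 5, 2), matrix(3, 5, 2))
  colnames(y) <- c("up", "up2")
  g <- factor(rep(c("pre", "post"), each = 5), levels = c("pre", "post"))
  fit <- betashift::rda(y + rnorm(20, sd = 1e-6), g, n_perm = 99, seed = 1)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)

  set.seed(2)
  y2 <- cbind(inc = c(rnorm(6, 1), rnorm(6, 5)),
              dec = c(rnorm(6, 5), rnorm(6, 1)),
              flat = rnorm(12))
  fit2 <- betashift::rda(y2, g <- factor(rep(c("pre", "post"), each = 6),
                                         levels = c("pre", "post")), n_perm = 0)
  sc <- tidy(fit2)
  expect_equal(sc$direction[sc$species == "inc"], "increase")
  expect_equal(sc$direction[sc$species == "dec"], "decrease")
  expect_gt(sc$share[sc$species == "inc"], sc$share[sc$species == "flat"])
  expect_equal(sum(sc$share), 1, tolerance = 1e-10)

  expect_error(betashift::rda(matrix(1, 6, 2), rep(c("a", "b"), 3)), "Constant")
})

test_that("null-label RDA R^2 concentrates near its (k-1)/(n-1) prior", {
  set.seed(3)
  r2 <- replicate(60, {
    y <- matrix(rnorm(24 * 4), 24, 4)
    betashift::rda(y, sample(rep(c("a", "b"), each = 12)), n_perm = 0)$r_squared
  })
  expect_lt(abs(mean(r2) - 1 / 23), 0.01)
})

test_that("two-way crossed partition is exact and detects injected interaction", {
  site <- rep(paste0("s", 1:3), each = 8)
  time <- rep(rep(1:4, each = 2), 3)
  set.seed(4)
  y <- matrix(rnorm(24 * 5), 24, 5)
  an <- two_way_crossed_anova(y, site, time, n_perm = 49, seed = 1)
  tt <- tidy(an)
  expect_equal(sum(tt$SS), an$SS_total, tolerance = 1e-10)
  expect_equal(tt$df, c(2, 3, 6, 12))

  # site-specific temporal shifts = strong interaction
  y2 <- y
  y2[site == "s1" & time > 2, 1] <- y2[site == "s1" & time > 2, 1] + 6
  y2[site == "s2" & time > 2, 2] <- y2[site == "s2" & time > 2, 2] - 6
  an2 <- two_way_crossed_anova(y2, site, time, n_perm = 399, seed = 2)
  expect_lte(tidy(an2)$p_value[3], 0.005)

  expect_error(two_way_crossed_anova(y[-1, ], site[-1], time[-1]), "unbalanced")
})

test_that("permutation p-values are reproducible under a fixed seed", {
  set.seed(5)
  y <- matrix(rnorm(24 * 3), 24, 3)
  site <- rep(paste0("s", 1:3), each = 8)
  time <- rep(rep(1:4, each = 2), 3)
  a1 <- two_way_crossed_anova(y, site, time, n_perm = 99, seed = 11)
  a2 <- two_way_crossed_anova(y, site, time, n_perm = 99, seed = 11)
  expect_identical(tidy(a1)$p_value, tidy(a2)$p_value)
})

test_that("PCoA embedding preserves distances and RDA R^2 is rotation-invariant", {
  dc <- decompose_matrix(toy_matrix())
  co <- embed_for_tests(dc)
  expect_equal(unname(as.matrix(dist(co))), unname(sqrt(dc$D_total)),
               tolerance = 1e-10)

  set.seed(6)
  y <- matrix(rnorm(30 * 4), 30, 4)
  g <- rep(c("a", "b", "c"), each = 10)
  rot <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  f1 <- betashift::rda(y, g, n_perm = 0)
  f2 <- betashift::rda(y %*% rot, g, n_perm = 0)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-10)

  # coordinates of the Euclidean distances of y are an equivalent response
  co_y <- embed_for_tests(structure(list(D_total = as.matrix(dist(y))^2),
                                    class = "decomposed_dissim"))
  f3 <- betashift::rda(co_y, g, n_perm = 99, seed = 3)
  f4 <- betashift::rda(scale(y, scale = FALSE), g, n_perm = 99, seed = 3)
  expect_equal(f3$r_squared, f4$r_squared, tolerance = 1e-8)
  expect_equal(f3$p_value, f4$p_value)
})
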