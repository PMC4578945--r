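test_that("indicator values match closed forms", {
  # perfect indicator: always present in group 1, absent elsewhere
  m <- cbind(perfect = c(rep(2, 10), rep(0, 10)),
             ubiquitous = rep(3, 20),
             empty = 0)
  labels <- rep(c("pre", "post"), each = 10)
  iv <- indval(m, labels, n_perm = 999, seed = 1)
  expect_equal(iv$indval[iv$species == "perfect"], 1)
  expect_equal(iv$p_raw[iv$species == "perfect"], 0.001)
  expect_equal(iv$indval[iv$species == "ubiquitous"], 0.5)
  expect_equal(iv$indval[iv$species == "empty"], 0)
  expect_true(iv$all_zero[iv$species == "empty"])
  expect_equal(iv$frequency[iv$species == "perfect"], 0.5)
})

test_that("indval is invariant to per-species rescaling and reproducible", {
  m <- random_table(16, 6, seed = 2)
  labels <- rep(c("a", "b"), each = 8)
  iv1 <- indval(m, labels, n_perm = 99, seed = 5)
  iv2 <- indval(m %*% diag(c(10, 0.1, 3, 1, 7, 2)), labels, n_perm = 99, seed = 5)
  expect_equal(iv1$indval, iv2$indval, tolerance = 1e-12)
  expect_identical(iv1$p_raw, iv2$p_raw)
  expect_error(indval(m, rep("a", 16)), "2 groups")
})

test_that("null species give approximately uniform raw p-values", {
  set.seed(3)
  ps <- replicate(40, {
    m <- matrix(rlnorm(20 * 3), 20, 3)
    indval(m, rep(c("a", "b"), each = 10), n_perm = 99)$p_raw[1]
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_lte(mean(ps <= 0.05), 0.2)
})

test_that("Holm adjustment follows the step-down arithmetic", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(0.01, 5)), rep(0.05, 5))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # never more discoveries after adjustment
  set.seed(4)
  p <- runif(50)^2
  expect_lte(sum(holm_adjust(p) <= 0.05), sum(p <= 0.05))
  # monotone in raw-p order
  ord <- order(p)
  expect_true(all(diff(holm_adjust(p)[ord]) >= 0))
})

test_that("shift-species selection applies the frequency floor and stays empty under the null", {
  iv <- tibble::tibble(species = c("common", "rare"),
                       indval = c(0.9, 0.95), best_group = "post",
                       frequency = c(0.5, 1 / 2000),
                       p_raw = c(0.001, 0.001), p_holm = c(0.002, 0.002),
                       all_zero = FALSE)
  scores <- tibble::tibble(species = c("common", "rare"),
                           score = c(2, -3),
                           direction = c("increase", "decrease"),
                           share = c(0.4, 0.6))
  sel <- select_shift_species(iv, scores)
  expect_equal(sel$species, "common")
  expect_equal(sel$direction, "increase")

  empty <- select_shift_species(dplyr::mutate(iv, p_holm = 0.8), scores)
  expect_equal(nrow(empty), 0)
})

test_that("per-site shift analysis returns aligned shift and species tables", {
  cfg <- small_config(seed = 6, inflection = c(2005, 2006),
                      inflection_scale = c(0.15, 0.25))
  ct <- simulate_community(cfg)
  res <- site_shift_analysis(ct, n_perm = 99, indval_n_perm = 499, seed = 1)
  expect_equal(nrow(res$shifts), 3)
  expect_true(all(res$shifts$r_squared >= 0 & res$shifts$r_squared <= 1))
  if (!is.null(res$species) && nrow(res$species)) {
    expect_true(all(res$species$site %in% res$shifts$site))
    expect_true(all(res$species$p_holm <= 0.05))
  }
})
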