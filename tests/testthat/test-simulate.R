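test_that("the survey-scale preset has the design dimensions and is seed-stable", {
  pp <- preset_paper_scale(seed = 4)
  expect_equal(dim(pp$table), c(546, 227))
  expect_equal(dplyr::n_distinct(pp$table$meta$site), 13)
  expect_equal(dplyr::n_distinct(pp$table$meta$time), 14)
  expect_true(all(pp$table$values >= 0))
  expect_true(all(pp$table$meta$coral_cover >= 0 & pp$table$meta$coral_cover <= 100))

  again <- preset_paper_scale(seed = 4)
  expect_identical(pp$table$values, again$table$values)
  other <- preset_paper_scale(seed = 5)
  expect_false(identical(pp$table$values, other$table$values))
})

test_that("habitat trajectories pass through the asymptote midpoint and refit cleanly", {
  cfg <- scenario_config(seed = 9)
  hp <- cfg$habitat[1, ]
  mid <- betashift:::logistic_curve(hp$T, hp$Y_b, hp$Y_a, hp$T, hp$sigma)
  expect_equal(mid, (hp$Y_b + hp$Y_a) / 2, tolerance = 1e-12)

  hab <- simulate_habitat(cfg)
  s1 <- hab[hab$site == "r01", ]
  fit <- fit_logistic(s1$time, s1$coral_cover)
  expect_true(fit$converged)
  expect_lt(abs(fit$parameters[["T"]] - hp$T), 0.5)
})

test_that("occupancy thinning matches the configured probabilities", {
  cfg <- scenario_config(n_sites = 4, block_sizes = c(NE = 3, W = 1),
                         n_species = 60, n_replicates = 10,
                         regime = "null", seed = 12)
  ct <- simulate_community(cfg)
  observed <- colMeans(ct$values > 0)
  # aggregate bias within 2%; per-species deviations within binomial noise
  expect_lt(abs(mean(observed - cfg$occupancy)), 0.02)
  se <- sqrt(cfg$occupancy * (1 - cfg$occupancy) / nrow(ct$values))
  expect_true(all(abs(observed - cfg$occupancy) < 5 * se + 1e-9))
})

test_that("compensatory expectations hold total biomass constant; synchronous ones collapse", {
  cfg <- scenario_config(seed = 3)
  for (s in cfg$sites[c(1, 13)]) {
    e <- betashift:::site_expected(cfg, s)
    tot <- rowSums(e)
    expect_lt(sd(tot) / mean(tot), 1e-12)
  }
  cfg_s <- scenario_config(seed = 3, regime = "synchronous")
  e_s <- betashift:::site_expected(cfg_s, "r01")
  tot_s <- rowSums(e_s)
  expect_lt(tot_s[length(tot_s)] / tot_s[1], 0.25)
})

test_that("regimes leave their replacement / abundance-difference signatures", {
  comp <- simulate_community(scenario_config(seed = 8))
  st <- beta_strata(comp)
  expect_gt(mean(st$frac_repl[st$scope == "spatial"]), 0.6)

  sync <- simulate_community(scenario_config(seed = 8, regime = "synchronous"))
  st2 <- beta_strata(sync)
  expect_gt(mean(st2$frac_diff[st2$scope == "spatial"]), 0.6)
})

test_that("dry-season surveys carry the additive seasonal biomass bump", {
  cfg <- scenario_config(n_sites = 3, block_sizes = c(NE = 2, W = 1),
                         n_species = 80, regime = "null",
                         noise_sd = 0.05, seed = 15)
  ct <- simulate_community(cfg)
  tot <- rowSums(ct$values)
  dry <- ct$meta$season == "dry"
  expect_gt(mean(tot[dry]), mean(tot[!dry]))
})

test_that("configuration errors are caught", {
  expect_error(scenario_config(n_sites = 5, block_sizes = c(NE = 3, W = 1)),
               "sum")
  expect_error(scenario_config(driver_directions = c(1, -1)), "length")
  expect_error(scenario_config(n_species = 20), "Not enough species")
})
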