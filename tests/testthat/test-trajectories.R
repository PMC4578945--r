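survey_times <- c(seq(2004, 2009, by = 0.5), 2010, 2011, 2012)

test_that("orthogonal polynomial design matches the classical contrasts", {
  op <- orthogonal_poly(1:5, 2)
  expect_equal(op[, 1] / op[5, 1], c(-2, -1, 0, 1, 2) / 2, tolerance = 1e-10)
  expect_equal(op[, 2] / op[5, 2], c(2, -1, -2, -1, 2) / 2, tolerance = 1e-10)
  expect_lt(abs(sum(op[, 1] * op[, 2])), 1e-10)
  expect_lt(max(abs(colSums(op))), 1e-10)
  expect_equal(crossprod(op), diag(2), tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(orthogonal_poly(c(1, 1, 2), 2), "distinct")
})

test_that("linear and quadratic fits recover noiseless generating curves", {
  t <- survey_times
  lin <- fit_linear(t, 2 * t + 1)
  expect_equal(lin$parameters[["slope"]], 2, tolerance = 1e-10)
  expect_equal(lin$r_squared, 1, tolerance = 1e-10)

  quad <- fit_quadratic(t, -(t - 2009)^2 + 40)
  expect_equal(quad$r_squared, 1, tolerance = 1e-10)
  expect_equal(quad$derived$vertex_time, 2009, tolerance = 1e-8)
  expect_true(quad$derived$concave)
})

test_that("logistic fit recovers exact parameters on noiseless collapse data", {
  t <- rep(survey_times, each = 3)
  y <- 50 + (5 - 50) / (1 + exp((2008 - t) / 0.5))
  fit <- fit_logistic(t, y)
  expect_true(fit$converged)
  truth <- c(Y_b = 50, Y_a = 5, T = 2008, sigma = 0.5)
  expect_equal(fit$parameters[names(truth)], truth, tolerance = 1e-4)
  expect_equal(fit$derived$decline_pct, 90, tolerance = 1e-6)
  # curve passes through the asymptote midpoint at T
  p <- fit$parameters
  mid <- p[["Y_b"]] + (p[["Y_a"]] - p[["Y_b"]]) /
    (1 + exp((p[["T"]] - p[["T"]]) / p[["sigma"]]))
  expect_equal(mid, (p[["Y_b"]] + p[["Y_a"]]) / 2, tolerance = 1e-10)
  expect_equal(logistic_decline_pct(50, 5), 90)
})

test_that("inflection time is recovered under replicate-level noise", {
  t <- rep(survey_times, each = 3)
  mu <- 50 + (5 - 50) / (1 + exp((2008 - t) / 0.5))
  set.seed(31)
  errs <- replicate(60, {
    fit <- fit_logistic(t, mu + rnorm(length(t), sd = 3))
    if (fit$converged) abs(fit$parameters[["T"]] - 2008) else NA_real_
  })
  expect_lte(median(errs, na.rm = TRUE), 0.3)
})

test_that("AIC selection prefers the generating model", {
  t <- rep(survey_times, each = 3)
  mu_log <- 40 + (4 - 40) / (1 + exp((2007.5 - t) / 0.4))
  set.seed(17)
  picks <- replicate(25, {
    select_model(t, mu_log + rnorm(length(t), sd = 1.5))$kind
  })
  expect_gte(mean(picks == "logistic"), 0.9)

  # linear data: quadratic-vs-linear F-test rarely significant
  set.seed(18)
  f_sig <- replicate(40, {
    fit <- select_model(t, 3 * (t - 2004) + rnorm(length(t), sd = 2))
    fit$derived$quad_vs_linear$p_value <= 0.05
  })
  expect_lte(mean(f_sig), 0.15)

  single <- fit_linear(t, 2 * t)
  expect_identical(select_model(fits = list(single))$kind, "linear")
})

test_that("stepwise regression respects signal structure and partitions R^2", {
  make_design <- function(seed) {
    set.seed(seed)
    tidyr::expand_grid(site = paste0("s", 1:4),
                       time = seq(2004, 2011, by = 1),
                       rep = 1:2)
  }
  d <- make_design(1)
  d$season <- ifelse(d$time %% 2 == 0, "wet", "dry")

  # signal in time and site only: the interaction is eliminated
  set.seed(2)
  d$y <- 2 * (d$time - 2004) + 3 * as.integer(factor(d$site)) + rnorm(nrow(d), sd = 0.5)
  fit <- stepwise_regression(d, "y")
  expect_true(all(c("t1", "site") %in% fit$terms$term))
  expect_false("t1:site" %in% fit$terms$term)
  # sequential partial R^2 sums to the model R^2
  expect_equal(sum(fit$terms$r_squared),
               summary(fit$model)$r.squared, tolerance = 1e-10)

  # pure-noise response: non-intercept terms mostly dropped
  set.seed(3)
  n_kept <- replicate(20, {
    d$y <- rnorm(nrow(d))
    nrow(stepwise_regression(d, "y")$terms)
  })
  expect_gte(mean(n_kept == 0), 0.5)
  expect_lte(mean(n_kept), 1)

  # full-signal response: all generating terms retained
  set.seed(4)
  d$y <- 2 * (d$time - 2004) + 3 * as.integer(factor(d$site)) +
    0.8 * (d$time - 2007)^2 +
    1.5 * (d$time - 2004) * (d$site == "s2") +
    2 * (d$season == "dry") + rnorm(nrow(d), sd = 0.5)
  fit2 <- stepwise_regression(d, "y")
  expect_true(all(c("t1", "t2", "site", "season", "t1:site") %in% fit2$terms$term))
})

test_that("per-site trajectory table selects the logistic collapse of coral cover", {
  cfg <- small_config(seed = 21, inflection = c(2005, 2006),
                      inflection_scale = c(0.2, 0.3))
  hab <- simulate_habitat(cfg)
  tab <- site_trajectories(dplyr::rename(hab, coral_cover2 = "coral_cover"),
                           "coral_cover2")
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$r_squared > 0.5))
})
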