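# Univariate temporal trajectory models for habitat cover, total biomass and
# species richness: linear and quadratic fits on orthogonal polynomials, a
# four-parameter logistic with inflection point
#   Y(t) = Y_b + (Y_a - Y_b) / (1 + exp((T - t) / sigma)),
# AIC-based model selection with a nested linear-vs-quadratic F-test, and a
# stepwise multiple regression over time, time^2, site, their interactions
# and season.

#' Orthogonal polynomial design columns for a time axis
#'
#' Columns are centred, mutually orthogonal and unit-normalised
#' (`stats::poly` contrasts), so sequential sums of squares of linear and
#' quadratic time effects are independent.
#'
#' @param time Numeric time values (>= degree + 1 distinct values).
#' @param degree Polynomial degree (default 2).
#' @return A numeric matrix with `degree` columns named `t1`, `t2`, ...
#' @export
orthogonal_poly <- function(time, degree = 2) {
  if (length(unique(time)) < degree + 1) {
    abort(sprintf("Need at least %d distinct time values for degree %d.",
                  degree + 1, degree))
  }
  m <- unclass(poly(time, degree = degree))
  colnames(m) <- paste0("t", seq_len(degree))
  attr(m, "coefs") <- NULL
  m
}

logistic_curve <- function(t, Y_b, Y_a, T, sigma) {
  Y_b + (Y_a - Y_b) / (1 + exp((T - t) / sigma))
}

new_trajectory_fit <- function(kind, parameters, fitted, y, n_par, converged,
                               model = NULL, derived = list()) {
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else NA_real_
  n <- length(y)
  # Gaussian log-likelihood AIC with sigma^2 profiled out (+1 parameter).
  aic <- if (converged) n * log(rss / n) + n * log(2 * pi) + n + 2 * (n_par + 1) else NA_real_
  structure(
    list(kind = kind, parameters = parameters, r_squared = r2, aic = aic,
         converged = converged, fitted = fitted, residuals = y - fitted,
         n = n, n_par = n_par, model = model, derived = derived),
    class = "trajectory_fit"
  )
}

#' Fit a linear temporal trajectory
#'
#' @param time,y Numeric vectors of equal length.
#' @return A `trajectory_fit` (kind `"linear"`) with slope and intercept on the
#'   raw time scale.
#' @export
fit_linear <- function(time, y) {
  if (length(unique(time)) < 2) abort("Need at least 2 distinct time values.")
  fit <- lm(y ~ time)
  new_trajectory_fit(
    "linear",
    c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2])),
    fitted = unname(predict(fit)), y = y, n_par = 2, converged = TRUE, model = fit
  )
}

#' Fit a quadratic temporal trajectory (orthogonal polynomials)
#'
#' Fits on degree-2 orthogonal polynomial columns; when the curvature is
#' concave the vertex time (the humped maximum, e.g. peak species richness)
#' is reported among the derived quantities.
#'
#' @inheritParams fit_linear
#' @return A `trajectory_fit` (kind `"quadratic"`) whose `derived$vertex_time`
#'   is the raw-scale vertex when the fit is concave.
#' @export
fit_quadratic <- function(time, y) {
  op <- orthogonal_poly(time, 2)
  fit <- lm(y ~ op)
  # Raw-scale coefficients for the vertex: refit on raw powers (same fit).
  raw <- lm(y ~ time + I(time^2))
  b <- coef(raw)
  vertex <- if (is.finite(b[3]) && b[3] < 0) unname(-b[2] / (2 * b[3])) else NA_real_
  new_trajectory_fit(
    "quadratic",
    c(intercept = unname(coef(fit)[1]), t1 = unname(coef(fit)[2]), t2 = unname(coef(fit)[3])),
    fitted = unname(predict(fit)), y = y, n_par = 3, converged = TRUE, model = fit,
    derived = list(vertex_time = vertex, concave = is.finite(b[3]) && b[3] < 0)
  )
}

#' Fit a logistic temporal trajectory with an inflection point
#'
#' Nonlinear least squares for
#' `Y(t) = Y_b + (Y_a - Y_b) / (1 + exp((T - t) / sigma))`: `Y_b` and `Y_a`
#' are the asymptotic response levels before and after the inflection, `T`
#' the inflection time and `sigma` (> 0, years) the transition scale; the
#' curve passes through `(Y_b + Y_a)/2` at `t = T`. A collapse of live coral
#' cover during a disturbance is the canonical shape. Start values: `Y_b` =
#' mean of the 3 earliest time points, `Y_a` = mean of the 3 latest, `T` =
#' median time, `sigma` = range/10, with `sigma` bounded in (1e-3, range\].
#' Non-convergence is reported via `converged = FALSE`, never an error.
#'
#' When `Y_b > 0` the derived `decline_pct = (Y_b - Y_a) / Y_b * 100`.
#'
#' @inheritParams fit_linear
#' @return A `trajectory_fit` (kind `"logistic"`).
#' @examples
#' t <- rep(c(seq(2004, 2009, 0.5), 2010:2012), each = 3)
#' y <- 50 + (5 - 50) / (1 + exp((2008 - t) / 0.5))
#' fit_logistic(t, y)$parameters
#' @export
fit_logistic <- function(time, y) {
  if (length(y) < 5) abort("Need at least 5 observations for the logistic fit.")
  ord <- order(time)
  t_means <- tapply(y[ord], time[ord], mean)
  t_vals <- as.numeric(names(t_means))
  rng <- diff(range(time))
  base_start <- list(
    Y_b = mean(head(t_means, 3)), Y_a = mean(utils::tail(t_means, 3)),
    T = median(time), sigma = max(rng / 10, 1e-2)
  )
  # plogis formulation saturates smoothly, so near-step transitions (small
  # sigma) do not overflow; multi-start on sigma covers gradual-to-abrupt.
  curve_at <- function(p) p[1] + (p[2] - p[1]) * plogis((time - p[3]) / p[4])
  lower <- c(-Inf, -Inf, min(time) - rng, 1e-3)
  upper <- c(Inf, Inf, max(time) + rng, rng)
  best <- NULL; diagnostic <- NULL
  for (s0 in unique(pmax(c(rng / 10, rng / 50, rng / 3), 2e-3))) {
    p0 <- pmin(pmax(c(base_start$Y_b, base_start$Y_a, base_start$T, s0), lower), upper)
    out <- tryCatch(
      minpack.lm::nls.lm(p0, lower = lower, upper = upper,
                         fn = function(p) y - curve_at(p),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e
    )
    if (inherits(out, "error")) {
      diagnostic <- conditionMessage(out)
    } else if (out$info %in% 1:4 &&
               (is.null(best) || out$deviance < best$deviance)) {
      best <- out
    } else if (!(out$info %in% 1:4)) {
      diagnostic <- out$message
    }
  }
  if (is.null(best)) {
    return(new_trajectory_fit("logistic", unlist(base_start),
                              fitted = rep(mean(y), length(y)),
                              y = y, n_par = 4, converged = FALSE,
                              derived = list(diagnostic = diagnostic)))
  }
  p <- setNames(best$par, c("Y_b", "Y_a", "T", "sigma"))
  decline <- if (p[["Y_b"]] > 0) (p[["Y_b"]] - p[["Y_a"]]) / p[["Y_b"]] * 100 else NA_real_
  new_trajectory_fit("logistic", p, fitted = curve_at(best$par), y = y,
                     n_par = 4, converged = TRUE, model = best,
                     derived = list(decline_pct = unname(decline)))
}

#' Percent decline between logistic asymptotes
#'
#' @param Y_b,Y_a Pre- and post-inflection asymptotes (`Y_b > 0`).
#' @return `(Y_b - Y_a) / Y_b * 100`.
#' @export
logistic_decline_pct <- function(Y_b, Y_a) {
  if (Y_b <= 0) abort("`Y_b` must be positive for a percent decline.")
  (Y_b - Y_a) / Y_b * 100
}

#' Select the best temporal trajectory model
#'
#' Fits (or accepts) linear, quadratic and logistic candidates on the same
#' data, drops non-converged fits, and selects the lowest AIC. The nested
#' linear-vs-quadratic comparison is additionally reported as an F-test.
#'
#' @param time,y Data vectors, used when `fits` is `NULL`.
#' @param fits Optional pre-computed list of `trajectory_fit` objects.
#' @return The winning `trajectory_fit`, with `derived$selection` holding the
#'   per-candidate AIC table and `derived$quad_vs_linear` the nested F-test
#'   (`F`, `p_value`).
#' @export
select_model <- function(time = NULL, y = NULL, fits = NULL) {
  if (is.null(fits)) {
    fits <- list(fit_linear(time, y), fit_quadratic(time, y), fit_logistic(time, y))
  }
  if (length(fits) == 1) return(fits[[1]])
  ok <- purrr::keep(fits, "converged")
  if (!length(ok)) abort("All candidate trajectory fits failed.")
  aics <- purrr::map_dbl(ok, "aic")
  best <- ok[[which.min(aics)]]
  sel <- tibble(kind = purrr::map_chr(ok, "kind"),
                aic = aics, r_squared = purrr::map_dbl(ok, "r_squared"))
  kinds <- purrr::map_chr(fits, "kind")
  qvl <- NULL
  if (all(c("linear", "quadratic") %in% kinds)) {
    flin <- fits[[match("linear", kinds)]]
    fquad <- fits[[match("quadratic", kinds)]]
    rss1 <- sum(flin$residuals^2); rss2 <- sum(fquad$residuals^2)
    df2 <- fquad$n - fquad$n_par
    f <- (rss1 - rss2) / (rss2 / df2)
    qvl <- list(F = f, df = c(1, df2), p_value = pf(f, 1, df2, lower.tail = FALSE))
  }
  best$derived$selection <- sel
  best$derived$quad_vs_linear <- qvl
  best
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit: %s> R^2 = %.3f | AIC = %.1f | converged: %s\n",
              x$kind, x$r_squared, x$aic, x$converged))
  print(round(x$parameters, 4))
  invisible(x)
}

#' @export
tidy.trajectory_fit <- function(x, ...) {
  tibble(term = names(x$parameters), estimate = unname(x$parameters))
}

#' @export
glance.trajectory_fit <- function(x, ...) {
  tibble(kind = x$kind, r_squared = x$r_squared, aic = x$aic,
         converged = x$converged, n = x$n,
         decline_pct = x$derived$decline_pct %||% NA_real_,
         vertex_time = x$derived$vertex_time %||% NA_real_)
}

#' @export
autoplot.trajectory_fit <- function(object, time = NULL, ...) {
  df <- tibble(fitted = object$fitted,
               observed = object$fitted + object$residuals,
               time = time %||% seq_along(object$fitted))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(y = "response", title = sprintf("%s fit (R² = %.2f)",
                                                  object$kind, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Stepwise multiple regression of a response over space-time structure
#'
#' Models a per-observation response (e.g. total biomass or species richness)
#' as a function of linear and quadratic orthogonal time effects, site, their
#' interactions and season, then reduces the model by bidirectional stepwise
#' selection. The default penalty is `k = log(n)` (BIC-flavoured), which keeps
#' essentially only significant effects; set `k = 2` for classical AIC.
#' Marginality is respected: an interaction can only stay with its main
#' effects present. The report gives the sequential (type-I) per-term
#' partition — partial R^2, df, F and p — which is additive in the
#' near-balanced designs this targets.
#'
#' @param data A data frame with columns `time`, `site`, `season` and the
#'   response.
#' @param response Name of the response column.
#' @param k Penalty per parameter in the stepwise criterion (default
#'   `log(n)`).
#' @return A list of class `stepwise_fit`: `model` (the reduced `lm`),
#'   `terms` (tibble: term, r_squared, df, F, p_value), `full_r_squared`.
#' @export
stepwise_regression <- function(data, response, k = NULL) {
  data <- as.data.frame(data)
  if (is.null(k)) k <- log(nrow(data))
  op <- orthogonal_poly(data$time, 2)
  d <- data.frame(y = data[[response]], t1 = op[, 1], t2 = op[, 2],
                  site = factor(data$site), season = factor(data$season))
  n_seas <- nlevels(d$season)
  full_terms <- c("t1", "t2", "site", "t1:site", "t2:site",
                  if (n_seas > 1) "season")
  full <- lm(as.formula(paste("y ~", paste(full_terms, collapse = " + "))), data = d)
  if (any(is.na(coef(full)))) {
    bad <- names(coef(full))[is.na(coef(full))]
    abort(paste0("Rank-deficient design; aliased terms: ", paste(bad, collapse = ", ")))
  }
  reduced <- step(full, direction = "both", trace = 0, k = k,
                  scope = list(lower = ~1, upper = formula(full)))
  an <- anova(reduced)
  tss <- sum(an[, "Sum Sq"])
  keep <- rownames(an) != "Residuals"
  terms_tbl <- tibble(
    term = rownames(an)[keep],
    r_squared = an[keep, "Sum Sq"] / tss,
    df = an[keep, "Df"],
    F = an[keep, "F value"],
    p_value = an[keep, "Pr(>F)"]
  )
  structure(list(model = reduced, terms = terms_tbl,
                 full_r_squared = sum(terms_tbl$r_squared)),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("<stepwise_fit> retained %d term(s), R^2 = %.3f\n",
              nrow(x$terms), x$full_r_squared))
  print(as.data.frame(x$terms))
  invisible(x)
}

#' @export
tidy.stepwise_fit <- function(x, ...) x$terms

#' @export
glance.stepwise_fit <- function(x, ...) {
  tibble(r_squared = x$full_r_squared, n_terms = nrow(x$terms),
         df_residual = x$model$df.residual)
}

#' Per-site trajectory table
#'
#' Fits and selects the best trajectory model of a response for each site,
#' returning one row per site in a tidy table (the per-reef trajectory
#' report).
#'
#' @param data A data frame with columns `site`, `time` and the response.
#' @param response Name of the response column.
#' @return A tibble: site, kind, r_squared, aic, decline_pct, vertex_time and
#'   the logistic parameters where applicable.
#' @export
site_trajectories <- function(data, response) {
  data |>
    dplyr::group_by(.data$site) |>
    dplyr::group_modify(function(df, key) {
      fit <- select_model(df$time, df[[response]])
      g <- glance(fit)
      if (fit$kind == "logistic") {
        g <- dplyr::bind_cols(g, tibble(Y_b = fit$parameters[["Y_b"]],
                                        Y_a = fit$parameters[["Y_a"]],
                                        T = fit$parameters[["T"]],
                                        sigma = fit$parameters[["sigma"]]))
      }
      g
    }) |>
    dplyr::ungroup()
}
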