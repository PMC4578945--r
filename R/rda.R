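# Redundancy analysis (RDA) with factor predictors and the two-way crossed
# space-time multivariate ANOVA by RDA for balanced designs, with permutation
# tests. For factor predictors the fitted values are group centroids, so
# R^2 = SS(fitted)/SS(total) measures how much compositional variance the
# grouping explains. Main effects are tested by permuting the residuals of
# the reduced model excluding the term; the interaction by permuting the
# residuals of the main-effects model.

# Orthonormal basis of the centred column space of a factor (df = levels - 1).
factor_basis <- function(f) {
  f <- factor(f)
  x <- stats::model.matrix(~f)[, -1, drop = FALSE]
  x <- scale(x, center = TRUE, scale = FALSE)
  qr_x <- qr(x)
  qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
}

# Residualise basis `q` against basis `z`, re-orthonormalise.
residual_basis <- function(q, z) {
  r <- q - z %*% crossprod(z, q)
  qr_r <- qr(r)
  keep <- abs(diag(qr.R(qr_r))[seq_len(ncol(r))]) > 1e-9
  qr.Q(qr_r)[, which(keep), drop = FALSE]
}

ss_of <- function(m) sum(m^2)

#' Redundancy analysis of a multivariate response on a factor
#'
#' Regresses a (column-centred) response matrix on a grouping factor: fitted
#' values are the group centroids, `R^2 = SS_fit / SS_total`, and significance
#' comes from permuting response rows. When the factor has exactly two levels,
#' per-species scores are reported as the centroid difference
#' (second level minus first level), so a positive score marks a species whose
#' quantity is higher in the second (e.g. post-shift) group, and each species'
#' share of the explained variance is returned.
#'
#' @param response Numeric matrix (rows = observations) or data frame.
#' @param group Factor (or coercible) of group labels aligned with rows.
#' @param n_perm Number of row permutations for the test (0 skips it).
#' @param seed Optional integer seed.
#' @return An object of class `rda_fit` with `r_squared`, `F`, `df`,
#'   `p_value`, `n_perm`, and (two-level factors) `species_scores`:
#'   a tibble `species, score, direction, share`.
#' @export
rda <- function(response, group, n_perm = 999, seed = NULL) {
  y <- as.matrix(response)
  g <- factor(group)
  if (nrow(y) != length(g)) abort("Rows of `response` must align with `group`.")
  if (nlevels(g) < 2) abort("`group` needs at least 2 levels.")
  yc <- scale(y, center = TRUE, scale = FALSE)
  ss_tot <- ss_of(yc)
  if (ss_tot <= 0) abort("Constant response: R^2 undefined.")
  q <- factor_basis(g)
  df1 <- ncol(q)
  df2 <- nrow(y) - df1 - 1
  stat <- function(ymat) {
    ss_fit <- ss_of(crossprod(q, ymat))
    c(r2 = ss_fit / ss_tot, F = (ss_fit / df1) / ((ss_tot - ss_fit) / df2))
  }
  obs <- stat(yc)
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      f_b <- stat(yc[sample.int(nrow(yc)), , drop = FALSE])[["F"]]
      exceed <- exceed + (f_b >= obs[["F"]])
    }
    p <- (exceed + 1) / (n_perm + 1)
  }
  scores <- NULL
  if (nlevels(g) == 2) {
    lv <- levels(g)
    delta <- colMeans(y[g == lv[2], , drop = FALSE]) -
      colMeans(y[g == lv[1], , drop = FALSE])
    fit_ss_sp <- colSums(crossprod(q, yc)^2)
    total_fit <- sum(fit_ss_sp)
    scores <- tibble(
      species = colnames(y) %||% paste0("sp", seq_along(delta)),
      score = unname(delta),
      direction = unname(ifelse(delta >= 0, "increase", "decrease")),
      share = if (total_fit > 0) unname(fit_ss_sp / total_fit) else NA_real_
    )
  }
  structure(
    list(r_squared = unname(obs[["r2"]]), F = unname(obs[["F"]]),
         df = c(df1, df2), p_value = p, n_perm = n_perm, seed = seed,
         levels = levels(g), species_scores = scores),
    class = "rda_fit"
  )
}

#' @export
print.rda_fit <- function(x, ...) {
  cat(sprintf("<rda_fit> R^2 = %.4f | F(%d, %d) = %.3f | p = %s (%d perms)\n",
              x$r_squared, x$df[1], x$df[2], x$F,
              format(x$p_value, digits = 3), x$n_perm))
  invisible(x)
}

#' @export
glance.rda_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, F = x$F, df1 = x$df[1], df2 = x$df[2],
         p_value = x$p_value, n_perm = x$n_perm)
}

#' @export
tidy.rda_fit <- function(x, ...) {
  if (is.null(x$species_scores)) {
    abort("Species scores are only available for two-level factors.")
  }
  x$species_scores
}

#' Two-way crossed multivariate ANOVA by RDA
#'
#' Partitions the total sum of squares of a (centred) multivariate response in
#' a balanced site x time design into site, time, site:time interaction and
#' residual components, with an F statistic per term. Significance is assessed
#' by permutation of residuals under the reduced model: each main effect is
#' tested against the model holding only the other main effect, the
#' interaction against the additive main-effects model.
#'
#' @param response Numeric matrix (rows = observations).
#' @param site,time Factors (or coercible) aligned with rows; every site x
#'   time cell must hold the same number of replicates.
#' @param n_perm Number of residual permutations per term.
#' @param seed Optional integer seed.
#' @return An object of class `spacetime_anova`: a tibble `terms` with
#'   `term, SS, df, F, p_value` (+ residual row) and the total SS.
#' @export
two_way_crossed_anova <- function(response, site, time, n_perm = 999, seed = NULL) {
  y <- as.matrix(response)
  site <- factor(site)
  time <- factor(time)
  if (nrow(y) != length(site) || nrow(y) != length(time)) {
    abort("`site` and `time` must align with response rows.")
  }
  counts <- table(site, time)
  if (length(unique(as.vector(counts))) != 1 || any(counts == 0)) {
    abort("Design is unbalanced: use equal replicate counts per site x time cell (e.g. analyse cell means).")
  }
  yc <- scale(y, center = TRUE, scale = FALSE)
  ss_tot <- ss_of(yc)
  q_a <- factor_basis(site)
  q_b <- factor_basis(time)
  cells <- factor(paste(site, time, sep = "\r"))
  q_cells <- factor_basis(cells)
  q_ab <- residual_basis(q_cells, cbind(q_a, q_b))
  df <- c(site = ncol(q_a), time = ncol(q_b), interaction = ncol(q_ab))
  df_res <- nrow(y) - 1 - sum(df)
  term_ss <- function(ymat) {
    c(site = ss_of(crossprod(q_a, ymat)),
      time = ss_of(crossprod(q_b, ymat)),
      interaction = ss_of(crossprod(q_ab, ymat)))
  }
  obs_ss <- term_ss(yc)
  ss_res <- ss_tot - sum(obs_ss)
  obs_f <- (obs_ss / df) / (ss_res / df_res)

  if (!is.null(seed)) set.seed(seed)
  exceed <- c(site = 0, time = 0, interaction = 0)
  if (n_perm > 0 && df_res > 0) {
    reduced <- list(site = q_b, time = q_a, interaction = cbind(q_a, q_b))
    fits <- lapply(reduced, function(z) z %*% crossprod(z, yc))
    resids <- lapply(fits, function(f) yc - f)
    for (b in seq_len(n_perm)) {
      perm <- sample.int(nrow(yc))
      for (term in names(exceed)) {
        y_b <- fits[[term]] + resids[[term]][perm, , drop = FALSE]
        ss_b <- term_ss(y_b)
        res_b <- ss_of(y_b) - sum(ss_b)
        f_b <- (ss_b[[term]] / df[[term]]) / (res_b / df_res)
        exceed[[term]] <- exceed[[term]] + (f_b >= obs_f[[term]])
      }
    }
  }
  p <- (exceed + 1) / (n_perm + 1)
  terms <- tibble(
    term = c("site", "time", "site:time", "residual"),
    SS = c(unname(obs_ss), ss_res),
    df = c(unname(df), df_res),
    F = c(unname(obs_f), NA_real_),
    p_value = c(unname(p), NA_real_)
  )
  structure(list(terms = terms, SS_total = ss_tot, n_perm = n_perm, seed = seed),
            class = "spacetime_anova")
}

#' @export
print.spacetime_anova <- function(x, ...) {
  cat(sprintf("<spacetime_anova> total SS = %.3f (%d permutations)\n",
              x$SS_total, x$n_perm))
  print(as.data.frame(x$terms))
  invisible(x)
}

#' @export
tidy.spacetime_anova <- function(x, ...) x$terms

#' @export
glance.spacetime_anova <- function(x, ...) {
  wide <- x$terms[x$terms$term != "residual", ]
  tibble(SS_total = x$SS_total,
         r_squared = sum(wide$SS) / x$SS_total,
         p_site = wide$p_value[wide$term == "site"],
         p_time = wide$p_value[wide$term == "time"],
         p_interaction = wide$p_value[wide$term == "site:time"],
         n_perm = x$n_perm)
}

#' Euclidean response matrix for community-level tests
#'
#' Principal coordinates of the square-root-embedded percentage-difference
#' matrix, retaining all positive-eigenvalue axes: Euclidean distances among
#' the returned rows reproduce `sqrt(d)` (exactly, for Euclidean-embeddable
#' inputs), so linear multivariate tests on these coordinates respect the
#' dissimilarity structure.
#'
#' @param decomp A [decompose_matrix()] result (or a `D_total` matrix).
#' @return A numeric coordinate matrix, rows named by observation.
#' @export
embed_for_tests <- function(decomp) {
  d_total <- if (inherits(decomp, "decomposed_dissim")) decomp$D_total else as.matrix(decomp)
  pcoa(sqrt_embed(d_total))$coordinates
}
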