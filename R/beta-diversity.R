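# Total beta diversity (variance of the community table) and Local
# Contributions to Beta Diversity (LCBD).
#
# Because the square-rooted percentage-difference matrix is Euclidean, the raw
# d values are the squared embedded distances: SS_total = sum of the lower
# triangle of D divided by N, BD_total = SS_total / (N - 1), and LCBD_i is the
# i-th diagonal element of the Gower-centred matrix of -d/2, divided by
# SS_total.

#' Total sum of squares of a dissimilarity matrix
#'
#' `SS_total = (1/N) * sum of lower-triangular dissimilarities`. The raw
#' percentage-difference values enter directly: they are the squares of the
#' Euclidean-embeddable square-rooted distances.
#'
#' @param d_total Square symmetric percentage-difference matrix.
#' @return `SS_total` (dimensionless).
#' @export
total_ss <- function(d_total) {
  d_total <- as.matrix(d_total)
  n <- nrow(d_total)
  if (n < 2) abort("Need at least 2 observations.")
  sum(lower_tri(d_total)) / n
}

#' Total beta diversity
#'
#' `BD_total = SS_total / (N - 1)`, the total variance of the community table
#' under the chosen dissimilarity; bounded by 0.5 for the percentage
#' difference index.
#'
#' @param ss_total Total sum of squares (from [total_ss()]).
#' @param n_obs Number of observations.
#' @return `BD_total`.
#' @export
bd_total <- function(ss_total, n_obs) {
  if (n_obs < 2) abort("Need at least 2 observations.")
  if (ss_total < 0) abort("`ss_total` must be non-negative.")
  ss_total / (n_obs - 1)
}

#' Local Contributions to Beta Diversity
#'
#' LCBD values measure how much each observation contributes to the total
#' compositional variance — large values flag observations with unusual
#' composition. They are the diagonal elements of the Gower-centred matrix of
#' `-d/2`, divided by `SS_total`, and sum to 1.
#'
#' @param d_total Square symmetric percentage-difference matrix.
#' @return Numeric vector of LCBD fractions (named by observation).
#' @export
lcbd <- function(d_total) {
  d_total <- as.matrix(d_total)
  n <- nrow(d_total)
  if (n < 2) abort("Need at least 2 observations.")
  g_diag <- centred_diagonal(d_total)
  ss <- sum(g_diag)
  if (ss <= 0) abort("All observations are identical: SS_total = 0, LCBD undefined.")
  out <- g_diag / ss
  names(out) <- rownames(d_total)
  out
}

# Diagonal of the Gower-centred -D/2 without forming the full centred matrix.
# G_ii = m_ii - 2*rowmean_i + grandmean, with M = -D/2 and m_ii = 0.
centred_diagonal <- function(d_total) {
  m_row <- rowMeans(-d_total / 2)
  m_row * (-2) + mean(-d_total / 2)
}

#' Beta diversity with LCBD permutation tests
#'
#' End-to-end wrapper: computes the decomposed dissimilarity of a community
#' table, `SS_total`, `BD_total`, per-observation LCBD values, and (optionally)
#' permutation p-values under the null of no compositional uniqueness. The
#' null is generated by permuting each species column independently across
#' observations, recomputing the LCBD vector each time;
#' `p_i = (#\{LCBD*_i >= LCBD_i\} + 1) / (n_perm + 1)`.
#'
#' @param table A [community_table()] or quantity matrix.
#' @param n_perm Number of permutations (0 skips the test).
#' @param seed Integer seed for reproducible permutations.
#' @return An object of class `beta_div` with fields `SS_total`, `BD_total`,
#'   `lcbd` (tibble `obs_id, LCBD, p_value`), `n_perm`, `seed`.
#' @examples
#' m <- rbind(a = c(4, 1, 0), b = c(1, 1, 3), c = c(0, 0, 3))
#' beta_div(m, n_perm = 99, seed = 1)
#' @export
beta_div <- function(table, n_perm = 999, seed = NULL) {
  values <- community_values(table)
  decomp <- decompose_matrix(values)
  ss <- total_ss(decomp$D_total)
  bd <- bd_total(ss, nrow(values))
  lc <- lcbd(decomp$D_total)
  p <- rep(NA_real_, length(lc))
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    exceed <- numeric(length(lc))
    n <- nrow(values)
    for (b in seq_len(n_perm)) {
      perm <- apply(values, 2, function(col) col[sample.int(n)])
      lc_b <- lcbd_of_values(perm)
      exceed <- exceed + (lc_b >= lc)
    }
    p <- (exceed + 1) / (n_perm + 1)
  }
  meta <- if (inherits(table, "community_table")) table$meta else NULL
  structure(
    list(
      SS_total = ss, BD_total = bd,
      lcbd = tibble(obs_id = names(lc) %||% as.character(seq_along(lc)),
                    LCBD = unname(lc), p_value = unname(p)),
      n_perm = n_perm, seed = seed, meta = meta
    ),
    class = "beta_div"
  )
}

# LCBD straight from a quantity matrix (used in the permutation loop).
lcbd_of_values <- function(values) {
  s <- rowSums(values)
  l1 <- as.matrix(dist(values, method = "manhattan"))
  ssum <- outer(s, s, "+")
  denom <- ifelse(ssum == 0, 1, ssum)
  d <- l1 / denom
  diag(d) <- 0
  g_diag <- centred_diagonal(d)
  ss <- sum(g_diag)
  if (ss <= 0) return(rep(0, nrow(values)))
  g_diag / ss
}

#' @export
print.beta_div <- function(x, ...) {
  cat(sprintf("<beta_div> N = %d | SS_total = %.4f | BD_total = %.4f\n",
              nrow(x$lcbd), x$SS_total, x$BD_total))
  if (x$n_perm > 0) {
    cat(sprintf("  LCBD: %d/%d significant at 0.05 (%d permutations)\n",
                sum(x$lcbd$p_value <= 0.05), nrow(x$lcbd), x$n_perm))
  }
  invisible(x)
}

#' @export
tidy.beta_div <- function(x, ...) {
  out <- x$lcbd
  if (!is.null(x$meta)) out <- dplyr::left_join(out, x$meta, by = "obs_id")
  out
}

#' @export
glance.beta_div <- function(x, ...) {
  tibble(SS_total = x$SS_total, BD_total = x$BD_total,
         n_obs = nrow(x$lcbd), n_perm = x$n_perm,
         n_significant = sum(x$lcbd$p_value <= 0.05))
}

#' LCBD bubble plot over sites and time
#'
#' Draws the classic LCBD display: one bubble per observation (or per
#' site-time mean) whose area is proportional to its LCBD value, with a
#' contrasting rim for values significant at `alpha`.
#'
#' @param object A `beta_div` fitted on a `community_table` (metadata needed).
#' @param alpha Significance level for the rim highlighting.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.beta_div <- function(object, alpha = 0.05, ...) {
  if (is.null(object$meta)) abort("autoplot.beta_div needs site/time metadata.")
  df <- tidy(object) |>
    dplyr::group_by(.data$site, .data$time) |>
    dplyr::summarise(LCBD = mean(.data$LCBD),
                     significant = any(.data$p_value <= alpha), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$site)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$LCBD, colour = .data$significant)) +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "black")) +
    ggplot2::labs(x = "Time", y = "Site", size = "LCBD",
                  colour = sprintf("p <= %.2f", alpha)) +
    ggplot2::theme_minimal()
}

#' LCBD permutation p-values
#'
#' Convenience wrapper around [beta_div()] returning only the per-observation
#' permutation p-values (independent within-species column permutation null).
#'
#' @inheritParams beta_div
#' @return Named numeric vector of p-values in (0, 1\].
#' @export
lcbd_significance <- function(table, n_perm = 999, seed = NULL) {
  bd <- beta_div(table, n_perm = n_perm, seed = seed)
  setNames(bd$lcbd$p_value, bd$lcbd$obs_id)
}
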