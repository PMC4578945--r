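# Stratified beta diversity: per-site (temporal response) and per-time-step
# (spatial response) component summaries, on two complementary scales:
#   * mean-pairwise: similarity = 1 - d_total, repl, diff, summing to 1 per
#     pair and per group mean (the triangle-plot scale);
#   * BD/variance: SS_comp within the group divided by (n_g - 1), additive
#     (BD_repl + BD_diff = BD_total) and bounded by 0.5.
# Component fractions (share of replacement vs abundance difference in beta
# diversity) are reported on the BD scale.

#' Similarity / replacement / difference triplets for observation pairs
#'
#' For each requested pair, returns `similarity = 1 - d_total`, `repl` and
#' `diff`; the three sum to 1 exactly, which is what ternary (triangle) plots
#' of community response display.
#'
#' @param decomp A [decompose_matrix()] result.
#' @param pairs Optional two-column matrix or data frame of observation ids
#'   (or integer indices); defaults to all pairs.
#' @return A tibble `obs_i, obs_j, similarity, repl, diff`.
#' @export
pair_triplets <- function(decomp, pairs = NULL) {
  stopifnot(inherits(decomp, "decomposed_dissim"))
  if (is.null(pairs)) {
    out <- tidy(decomp)
  } else {
    pairs <- as.matrix(pairs)
    if (nrow(pairs) == 0) abort("Empty pair set.")
    i <- resolve_obs(pairs[, 1], decomp$obs_id)
    j <- resolve_obs(pairs[, 2], decomp$obs_id)
    idx <- cbind(i, j)
    out <- tibble(obs_i = decomp$obs_id[i], obs_j = decomp$obs_id[j],
                  d_total = decomp$D_total[idx],
                  d_repl = decomp$D_repl[idx],
                  d_diff = decomp$D_diff[idx])
  }
  dplyr::transmute(out, obs_i = .data$obs_i, obs_j = .data$obs_j,
                   similarity = 1 - .data$d_total,
                   repl = .data$d_repl, diff = .data$d_diff)
}

resolve_obs <- function(x, ids) {
  if (is.numeric(x)) return(as.integer(x))
  m <- match(as.character(x), ids)
  if (anyNA(m)) abort("Unknown observation id in pair set.")
  m
}

#' Stratify observations into spatial or temporal groups
#'
#' `by = "site"` yields one group per site (all its time steps and replicates:
#' the temporal response at that site); `by = "time"` yields one group per
#' time step (all sites and replicates: the spatial response at that time).
#' Groups with fewer than 2 observations are dropped with a warning.
#'
#' @param table A [community_table()].
#' @param by `"site"` or `"time"`.
#' @return A named list of character vectors of observation ids.
#' @export
stratify <- function(table, by = c("site", "time")) {
  stopifnot(inherits(table, "community_table"))
  by <- match.arg(by)
  groups <- split(table$meta$obs_id, table$meta[[by]])
  small <- vapply(groups, length, 1L) < 2
  if (any(small)) {
    warn(paste0("Dropping group(s) with < 2 observations: ",
                paste(names(groups)[small], collapse = ", ")))
    groups <- groups[!small]
  }
  groups
}

#' Beta-diversity summary of one observation group
#'
#' Summarises all within-group pairs: the mean (similarity, repl, diff)
#' triplet with descriptive t-based 95% CIs, and the BD-scale quantities
#' `BD_total`, `BD_repl`, `BD_diff` (within-group SS divided by n_g - 1) with
#' the replacement / difference fractions of total beta diversity.
#'
#' @param decomp A [decompose_matrix()] result.
#' @param obs Character vector of observation ids (or integer indices) in the
#'   group; at least 2.
#' @param conf_level Confidence level for the descriptive CIs.
#' @return A one-row tibble.
#' @export
group_summary <- function(decomp, obs, conf_level = 0.95) {
  stopifnot(inherits(decomp, "decomposed_dissim"))
  i <- resolve_obs(obs, decomp$obs_id)
  n_g <- length(i)
  if (n_g < 2) abort("Group must contain at least 2 observations.")
  dt <- decomp$D_total[i, i]
  dr <- decomp$D_repl[i, i]
  dd <- decomp$D_diff[i, i]
  pt <- lower_tri(dt); pr <- lower_tri(dr); pd <- lower_tri(dd)
  n_pairs <- length(pt)
  ci_half <- function(x) {
    if (length(x) < 2) return(NA_real_)
    qt(1 - (1 - conf_level) / 2, length(x) - 1) * sd(x) / sqrt(length(x))
  }
  ss_t <- sum(pt) / n_g; ss_r <- sum(pr) / n_g; ss_d <- sum(pd) / n_g
  bd_t <- ss_t / (n_g - 1); bd_r <- ss_r / (n_g - 1); bd_d <- ss_d / (n_g - 1)
  degenerate <- bd_t <= 0
  tibble(
    n_obs = n_g, n_pairs = n_pairs,
    mean_sim = 1 - mean(pt), mean_repl = mean(pr), mean_diff = mean(pd),
    ci_sim = ci_half(1 - pt), ci_repl = ci_half(pr), ci_diff = ci_half(pd),
    bd_total = bd_t, bd_repl = bd_r, bd_diff = bd_d,
    frac_repl = if (degenerate) NA_real_ else bd_r / bd_t,
    frac_diff = if (degenerate) NA_real_ else bd_d / bd_t,
    degenerate = degenerate
  )
}

#' Stratified beta-diversity summaries
#'
#' Applies [group_summary()] to every spatial and/or temporal stratum of a
#' community table, giving the per-site temporal response and the per-time
#' spatial response of the community.
#'
#' @param table A [community_table()].
#' @param decomp Optional precomputed [decompose_matrix()] of `table`.
#' @param scopes Which stratifications to run (`"site"`, `"time"` or both).
#' @return A tibble with one row per group: `scope`, `group`, and the
#'   [group_summary()] columns.
#' @examples
#' ct <- simulate_community(scenario_config(n_sites = 3, n_species = 20, seed = 1))
#' beta_strata(apply_transform(ct, "sqrt"))
#' @export
beta_strata <- function(table, decomp = NULL, scopes = c("site", "time")) {
  stopifnot(inherits(table, "community_table"))
  scopes <- match.arg(scopes, several.ok = TRUE)
  if (is.null(decomp)) decomp <- decompose_matrix(table)
  purrr::map_dfr(scopes, function(scope) {
    groups <- stratify(table, scope)
    purrr::imap_dfr(groups, function(obs, nm) {
      dplyr::bind_cols(
        tibble(scope = if (scope == "site") "spatial" else "temporal", group = nm),
        group_summary(decomp, obs)
      )
    })
  })
}

#' Ternary coordinates for similarity / replacement / difference triplets
#'
#' Standard ternary projection: `x = repl + diff/2`, `y = diff * sqrt(3)/2`.
#' Pure similarity maps to (0, 0), pure replacement to (1, 0) and pure
#' abundance difference to the apex (0.5, sqrt(3)/2).
#'
#' @param triplets A data frame with columns `similarity`, `repl`, `diff`.
#' @return The input with `x` and `y` columns appended.
#' @export
triangle_coordinates <- function(triplets) {
  stopifnot(all(c("similarity", "repl", "diff") %in% names(triplets)))
  dplyr::mutate(as_tibble(triplets),
                x = .data$repl + .data$diff / 2,
                y = .data$diff * sqrt(3) / 2)
}

#' Triangle (ternary) plot of group-level community responses
#'
#' Displays each group's within-pair triplets (small points) and the group
#' mean (large point) in the similarity / replacement / abundance-difference
#' triangle.
#'
#' @param table A [community_table()].
#' @param by Stratification (`"site"` or `"time"`).
#' @param decomp Optional precomputed decomposition.
#' @return A ggplot object.
#' @export
plot_triangle <- function(table, by = c("site", "time"), decomp = NULL) {
  by <- match.arg(by)
  if (is.null(decomp)) decomp <- decompose_matrix(table)
  groups <- stratify(table, by)
  pts <- purrr::imap_dfr(groups, function(obs, nm) {
    i <- resolve_obs(obs, decomp$obs_id)
    pairs <- which(lower.tri(diag(length(i))), arr.ind = TRUE)
    dplyr::mutate(
      pair_triplets(decomp, cbind(i[pairs[, 2]], i[pairs[, 1]])),
      group = nm
    )
  })
  pts <- triangle_coordinates(pts)
  means <- pts |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(dplyr::across(c("similarity", "repl", "diff"), mean),
                     .groups = "drop") |>
    triangle_coordinates()
  frame <- tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = frame, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.15, size = 0.6, colour = "grey50") +
    ggplot2::geom_point(data = means, ggplot2::aes(colour = .data$group), size = 3) +
    ggplot2::annotate("text", x = c(-0.03, 1.03, 0.5), y = c(-0.04, -0.04, sqrt(3) / 2 + 0.05),
                      label = c("similarity", "replacement", "difference"), size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = if (by == "site") "Site" else "Time step")
}
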