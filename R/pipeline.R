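# Pipeline orchestration: transform -> pairwise decomposition -> total beta
# diversity / LCBD -> stratified summaries -> trajectory fits -> two-way
# space-time test -> MRT + chronological clustering -> species attribution,
# with CSV/JSON artifacts and figure builders.

#' Run the full spatio-temporal beta-diversity pipeline
#'
#' Executes, on a community table: the quantity transform, the pairwise
#' percentage-difference decomposition, total beta diversity and LCBD with
#' permutation tests, spatial and temporal stratum summaries, per-site
#' trajectory model selection for the habitat covariate (when present), the
#' two-way crossed space-time RDA-ANOVA on PCoA coordinates, an MRT over site
#' and time, and the per-site shift analysis (chronological clustering,
#' indicator values, RDA species scores, joint selection). Stages can be
#' toggled; every stochastic stage uses a seed derived from `seed`.
#'
#' @param table A [community_table()] with raw (untransformed) quantities.
#' @param transform `"sqrt"` (default) or `"identity"`.
#' @param n_perm Permutations for all tests (>= 99 recommended for reported
#'   p-values).
#' @param alpha Significance level used in reports.
#' @param seed Integer seed.
#' @param stages Character vector of stages to run, a subset of
#'   `c("beta", "strata", "trajectories", "spacetime", "shift")`.
#' @param out_dir Optional directory; when given, CSV/JSON artifacts are
#'   written there.
#' @return A list of class `betashift_report` with one element per stage plus
#'   `summary` (a flat list of headline numbers).
#' @export
run_pipeline <- function(table, transform = "sqrt", n_perm = 999, alpha = 0.05,
                         seed = 1L,
                         stages = c("beta", "strata", "trajectories",
                                    "spacetime", "shift"),
                         out_dir = NULL) {
  stopifnot(inherits(table, "community_table"))
  stages <- match.arg(stages, several.ok = TRUE)
  tt <- apply_transform(table, transform)
  decomp <- decompose_matrix(tt)
  report <- list(transform = transform, n_perm = n_perm, alpha = alpha,
                 seed = seed, decomp = decomp)

  if ("beta" %in% stages) {
    report$beta <- beta_div(tt, n_perm = n_perm, seed = stream_seed(seed, 11L))
  }
  if ("strata" %in% stages) {
    report$strata <- beta_strata(tt, decomp = decomp)
  }
  if ("trajectories" %in% stages && "coral_cover" %in% names(table$meta) &&
      !anyNA(table$meta$coral_cover)) {
    report$trajectories <- site_trajectories(table$meta, "coral_cover")
  }
  if ("spacetime" %in% stages) {
    coords <- embed_for_tests(decomp)
    meta <- tt$meta
    report$spacetime <- two_way_crossed_anova(
      coords, meta$site, meta$time,
      n_perm = n_perm, seed = stream_seed(seed, 12L)
    )
    report$mrt <- mrt_fit(coords,
                          data.frame(site = meta$site, time = meta$time),
                          max_leaves = 4, alpha = alpha,
                          n_perm = min(n_perm, 199),
                          seed = stream_seed(seed, 13L))
  }
  if ("shift" %in% stages) {
    report$shift <- site_shift_analysis(table, transform = transform,
                                        n_perm = n_perm, alpha = alpha,
                                        seed = stream_seed(seed, 14L))
  }

  report$summary <- pipeline_summary(report)
  class(report) <- "betashift_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

pipeline_summary <- function(report) {
  s <- list(transform = report$transform, n_perm = report$n_perm,
            seed = report$seed)
  if (!is.null(report$beta)) {
    s$SS_total <- report$beta$SS_total
    s$BD_total <- report$beta$BD_total
    s$n_lcbd_significant <- sum(report$beta$lcbd$p_value <= report$alpha)
  }
  if (!is.null(report$strata)) {
    sp <- report$strata[report$strata$scope == "spatial", ]
    tp <- report$strata[report$strata$scope == "temporal", ]
    s$mean_similarity_spatial_groups <- mean(sp$mean_sim)
    s$temporal_frac_repl <- mean(sp$frac_repl, na.rm = TRUE)
    s$temporal_frac_diff <- mean(sp$frac_diff, na.rm = TRUE)
    s$spatial_frac_repl <- mean(tp$frac_repl, na.rm = TRUE)
  }
  if (!is.null(report$spacetime)) {
    g <- glance(report$spacetime)
    s$spacetime_r_squared <- g$r_squared
    s$p_interaction <- g$p_interaction
  }
  if (!is.null(report$shift)) {
    s$shift_r_squared_range <- range(report$shift$shifts$r_squared)
    sel <- report$shift$species
    s$n_shift_species <- if (is.null(sel) || !nrow(sel)) 0L else
      dplyr::n_distinct(sel$species)
  }
  s
}

#' @export
print.betashift_report <- function(x, ...) {
  cat("<betashift_report>\n")
  str(x$summary, give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$beta)) {
    readr::write_csv(dplyr::mutate(report$beta$lcbd,
                                   significant = .data$p_value <= report$alpha),
                     file.path(out_dir, "lcbd.csv"), progress = FALSE)
  }
  if (!is.null(report$strata)) {
    readr::write_csv(report$strata, file.path(out_dir, "group_summaries.csv"),
                     progress = FALSE)
  }
  if (!is.null(report$trajectories)) {
    readr::write_csv(report$trajectories, file.path(out_dir, "trajectories.csv"),
                     progress = FALSE)
  }
  if (!is.null(report$spacetime)) {
    jsonlite::write_json(tidy(report$spacetime),
                         file.path(out_dir, "spacetime_anova.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(report$shift)) {
    readr::write_csv(report$shift$shifts, file.path(out_dir, "shifts.csv"),
                     progress = FALSE)
    if (!is.null(report$shift$species) && nrow(report$shift$species)) {
      readr::write_csv(report$shift$species,
                       file.path(out_dir, "shift_species.csv"), progress = FALSE)
    }
  }
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' PCoA ordination plot of a decomposition component
#'
#' Principal coordinates of the chosen matrix (total beta diversity is
#' square-root embedded first; the component matrices are ordinated as-is),
#' optionally coloured by a grouping such as MRT leaves.
#'
#' @param decomp A [decompose_matrix()] result.
#' @param component `"total"`, `"repl"` or `"diff"`.
#' @param groups Optional per-observation grouping for colour.
#' @return A ggplot object.
#' @export
plot_pcoa <- function(decomp, component = c("total", "repl", "diff"),
                      groups = NULL) {
  component <- match.arg(component)
  d <- switch(component,
              total = sqrt_embed(decomp$D_total),
              repl = decomp$D_repl,
              diff = decomp$D_diff)
  ord <- suppressWarnings(pcoa(d))
  co <- ord$coordinates
  rel <- ord$eigenvalues / sum(pmax(ord$eigenvalues, 0))
  df <- tibble(obs_id = rownames(co), Axis1 = co[, 1],
               Axis2 = if (ncol(co) > 1) co[, 2] else 0,
               group = if (is.null(groups)) "all" else as.character(groups))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis1, y = .data$Axis2,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("PCoA 1 (%.1f%%)", 100 * rel[1]),
      y = sprintf("PCoA 2 (%.1f%%)", 100 * max(rel[2], 0)),
      colour = NULL,
      title = sprintf("PCoA of the %s matrix", component)
    ) +
    ggplot2::theme_minimal()
}
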