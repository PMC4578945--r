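# Indicator species analysis for pre/post-shift groups: Dufrene-Legendre
# indicator values (specificity x fidelity), permutation tests, Holm
# (sequential Bonferroni) correction, and joint selection of shift-driving
# species from indicator values and RDA scores.

indval_matrix <- function(values, labels) {
  labels <- factor(labels)
  groups <- levels(labels)
  mean_ab <- vapply(groups, function(g) {
    colMeans(values[labels == g, , drop = FALSE])
  }, numeric(ncol(values)))               # species x groups
  occ <- vapply(groups, function(g) {
    colMeans(values[labels == g, , drop = FALSE] > 0)
  }, numeric(ncol(values)))
  denom <- rowSums(mean_ab)
  a <- mean_ab / ifelse(denom == 0, 1, denom) # specificity
  iv <- a * occ
  list(indval = apply(iv, 1, max),
       best = groups[apply(iv, 1, which.max)],
       A = a, B = occ, all_zero = denom == 0)
}

# Null distribution of max-group indicator values under joint label
# permutation, batched: per-group sums for all permutations come from one
# matrix product per group, so tens of thousands of permutations stay cheap.
indval_null_exceed <- function(values, labels, observed, n_perm) {
  labels <- factor(labels)
  groups <- levels(labels)
  n <- nrow(values)
  sizes <- table(labels)
  vt <- t(values)            # species x obs
  pt <- t(values > 0)
  perm_labels <- vapply(seq_len(n_perm),
                        function(b) as.integer(sample(labels)),
                        integer(n))
  iv_max <- matrix(0, ncol(values), n_perm)
  for (g in seq_along(groups)) {
    z <- (perm_labels == g) * 1    # obs x n_perm indicator
    mean_g <- (vt %*% z) / sizes[[g]]
    occ_g <- (pt %*% z) / sizes[[g]]
    if (g == 1) {
      means <- list(mean_g); occs <- list(occ_g)
    } else {
      means[[g]] <- mean_g; occs[[g]] <- occ_g
    }
  }
  denom <- Reduce(`+`, means)
  denom[denom == 0] <- 1
  for (g in seq_along(groups)) {
    iv_max <- pmax(iv_max, (means[[g]] / denom) * occs[[g]])
  }
  rowSums(iv_max >= observed)
}

#' Indicator values of species for a grouping
#'
#' For each species and group: specificity `A` (the group's share of the
#' species' mean abundance across groups), fidelity `B` (fraction of the
#' group's observations where the species occurs), and the indicator value
#' `IndVal = max over groups of A * B` in \[0, 1\]. A perfect indicator
#' (always present in one group, absent elsewhere) scores 1; an everywhere-
#' absent species scores 0 and is flagged.
#'
#' @param table A [community_table()] or quantity matrix.
#' @param labels Group labels (>= 2 non-empty groups) aligned with
#'   observations.
#' @param n_perm Number of joint label permutations for the per-species test
#'   (0 skips it).
#' @param seed Optional integer seed.
#' @return A tibble: `species, indval, best_group, frequency, p_raw, p_holm,
#'   all_zero`, where `frequency` is the fraction of all observations where
#'   the species is present.
#' @examples
#' m <- rbind(matrix(c(5, 0), 4, 2, byrow = TRUE),
#'            matrix(c(0, 5), 4, 2, byrow = TRUE))
#' colnames(m) <- c("pre_sp", "post_sp")
#' indval(m, rep(c("pre", "post"), each = 4), n_perm = 99, seed = 1)
#' @export
indval <- function(table, labels, n_perm = 999, seed = NULL) {
  values <- community_values(table)
  labels <- factor(labels)
  if (nlevels(labels) < 2) abort("Need at least 2 groups.")
  if (any(table(labels) == 0)) abort("Every group must be non-empty.")
  if (nrow(values) != length(labels)) abort("`labels` must align with observations.")
  obs <- indval_matrix(values, labels)
  p_raw <- rep(NA_real_, ncol(values))
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    exceed <- indval_null_exceed(values, labels, obs$indval, n_perm)
    p_raw <- (exceed + 1) / (n_perm + 1)
  }
  tibble(
    species = colnames(values) %||% paste0("sp", seq_len(ncol(values))),
    indval = unname(obs$indval),
    best_group = unname(obs$best),
    frequency = unname(colMeans(values > 0)),
    p_raw = p_raw,
    p_holm = if (all(is.na(p_raw))) p_raw else holm_adjust(p_raw),
    all_zero = unname(obs$all_zero)
  )
}

#' Raw permutation p-values for indicator values
#'
#' Group labels are permuted jointly across observations (preserving group
#' sizes) and each species' indicator value recomputed;
#' `p = (exceedances + 1) / (n_perm + 1)`.
#'
#' @inheritParams indval
#' @return Named numeric vector of raw p-values.
#' @export
indval_test <- function(table, labels, n_perm = 999, seed = NULL) {
  res <- indval(table, labels, n_perm = n_perm, seed = seed)
  setNames(res$p_raw, res$species)
}

#' Holm (sequential Bonferroni) correction
#'
#' Step-down correction controlling the family-wise error rate: p-values are
#' sorted ascending, the k-th smallest multiplied by `m - k + 1`, monotonicity
#' enforced and values capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03)) # 0.03, 0.06, 0.06
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "holm")
}

#' Select species driving a compositional shift
#'
#' Joint selection from indicator values and RDA scores: keeps species whose
#' Holm-adjusted indicator p-value is at most `alpha` and whose overall
#' occurrence frequency is at least `freq_floor` (rare-species exclusion),
#' ranked by absolute RDA score with the signed direction retained. Each
#' selected species' `share` is its fraction of the shift R-squared (from the
#' two-level RDA).
#'
#' @param indval_result Tibble from [indval()].
#' @param rda_scores Tibble of species scores from a two-level [rda()]
#'   (`species, score, direction, share`).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param freq_floor Minimum occurrence frequency (default 0.001).
#' @return A ranked tibble `species, indval, best_group, p_raw, p_holm,
#'   rda_score, direction, share, frequency`; empty when nothing passes.
#' @export
select_shift_species <- function(indval_result, rda_scores, alpha = 0.05,
                                 freq_floor = 0.001) {
  joined <- dplyr::inner_join(
    indval_result,
    dplyr::rename(rda_scores, rda_score = "score"),
    by = "species"
  )
  joined |>
    dplyr::filter(!is.na(.data$p_holm), .data$p_holm <= alpha,
                  .data$frequency >= freq_floor) |>
    dplyr::arrange(dplyr::desc(abs(.data$rda_score))) |>
    dplyr::select("species", "indval", "best_group", "p_raw", "p_holm",
                  "rda_score", "direction", "share", "frequency")
}

#' Per-site shift attribution
#'
#' For each site: chronological split of the (transformed) community series,
#' two-level RDA of the community on the pre/post factor, indicator values,
#' and the joint species selection. This is the per-reef shift analysis of
#' the full pipeline.
#'
#' @param table A [community_table()] with raw (untransformed) quantities.
#' @param transform Transform applied to the community response for the
#'   chronological split and the RDA (default `"sqrt"`).
#' @param indval_transform Transform for the indicator-value computation;
#'   defaults to `"identity"` (raw biomass — specificity ratios are
#'   per-species scale-free, so this choice only weights observations).
#' @param n_perm Permutations for the chronological-split test.
#' @param indval_n_perm Permutations for the indicator tests. With `m` species
#'   the Holm correction can only reject at `alpha` if
#'   `n_perm >= m / alpha - 1`, so this defaults much higher than `n_perm`.
#' @param alpha,freq_floor Passed to [select_shift_species()].
#' @param seed Optional integer seed.
#' @return A list with `shifts` (tibble: site, boundary, r_squared, p_value)
#'   and `species` (tibble of selected species per site).
#' @export
site_shift_analysis <- function(table, transform = "sqrt",
                                indval_transform = "identity",
                                n_perm = 999, indval_n_perm = 9999,
                                alpha = 0.05, freq_floor = 0.001, seed = NULL) {
  stopifnot(inherits(table, "community_table"))
  if (!is.null(seed)) set.seed(seed)
  resp <- apply_transform(table, transform)
  iv_tab <- apply_transform(table, indval_transform)
  sites <- unique(table$meta$site)
  shifts <- list(); species <- list()
  for (s in sites) {
    rows <- table$meta$obs_id[table$meta$site == s]
    y <- resp$values[rows, , drop = FALSE]
    tm <- table$meta$time[match(rows, table$meta$obs_id)]
    cs <- chronological_split(y, tm, n_perm = n_perm)
    shifts[[s]] <- dplyr::bind_cols(tibble(site = s), glance(cs))
    fit <- rda(y, cs$groups, n_perm = 0)
    iv <- indval(iv_tab$values[rows, , drop = FALSE], cs$groups,
                 n_perm = indval_n_perm)
    sel <- select_shift_species(iv, fit$species_scores, alpha = alpha,
                                freq_floor = freq_floor)
    if (nrow(sel)) species[[s]] <- dplyr::bind_cols(tibble(site = s), sel)
  }
  list(shifts = dplyr::bind_rows(shifts), species = dplyr::bind_rows(species))
}

#' Bar plot of species contributions to a shift
#'
#' Signed per-species contribution bars (positive = biomass increased after
#' the shift), faceted by site when a `site` column is present.
#'
#' @param species_table Output `species` tibble of [site_shift_analysis()] or
#'   a [select_shift_species()] result.
#' @param top_n Show at most this many species per site (by |score|).
#' @return A ggplot object.
#' @export
plot_shift_species <- function(species_table, top_n = 10) {
  df <- as_tibble(species_table)
  if (!"site" %in% names(df)) df$site <- "all"
  df <- df |>
    dplyr::group_by(.data$site) |>
    dplyr::slice_max(abs(.data$rda_score), n = top_n, with_ties = FALSE) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rda_score,
                                   y = stats::reorder(.data$species, abs(.data$rda_score)),
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~site, scales = "free") +
    ggplot2::scale_fill_manual(values = c(increase = "steelblue", decrease = "firebrick")) +
    ggplot2::labs(x = "RDA score (post - pre)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
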