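# Multivariate regression trees (MRT) on community responses and chronological
# clustering (time-constrained 2-group MRT) per site. Splits greedily minimise
# the total within-node sum of squares; each accepted split's variance
# reduction is tested by permuting the node's response rows against its
# predictor values, and growth stops at `max_leaves` or the first
# non-significant split.
#
# All split searches run on per-level sufficient statistics: with level
# quantity sums S (levels x species), their Gram matrix G = S S', level counts
# and level sums of squared row norms, the within-SS of any level subset P is
#   SS(P) = Q_P - (1' G_P 1) / n_P,
# so candidate partitions cost O(levels^2) rather than O(n x species).

node_ss <- function(y, idx, sq = NULL) {
  if (length(idx) < 2) return(0)
  sub <- y[idx, , drop = FALSE]
  q <- if (is.null(sq)) sum(sub^2) else sum(sq[idx])
  q - sum(colSums(sub)^2) / length(idx)
}

# Per-level sufficient statistics of a node for one predictor.
level_stats <- function(y, idx, xi, sq) {
  f <- factor(xi)
  s <- rowsum(y[idx, , drop = FALSE], f)          # levels x species
  list(levels = levels(f),
       n = as.vector(table(f)),
       q = as.vector(rowsum(sq[idx], f)),
       gram = tcrossprod(s))
}

subset_ss <- function(stats, sel) {
  # within-SS of the selected levels and of their complement
  n1 <- sum(stats$n[sel]); n2 <- sum(stats$n[!sel])
  q1 <- sum(stats$q[sel]); q2 <- sum(stats$q[!sel])
  g1 <- sum(stats$gram[sel, sel]); g2 <- sum(stats$gram[!sel, !sel])
  ss1 <- if (n1 > 0) q1 - g1 / n1 else 0
  ss2 <- if (n2 > 0) q2 - g2 / n2 else 0
  ss1 + ss2
}

# Best binary split of `idx` on one predictor. Returns NULL when no admissible
# split exists.
best_split_one <- function(y, idx, x, name, sq) {
  xi <- x[idx]
  ordered_pred <- is.numeric(x) || is.ordered(x)
  if (ordered_pred) {
    stats <- level_stats(y, idx, as.numeric(xi), sq)
    vals <- as.numeric(stats$levels)
    ord <- order(vals)
  } else {
    stats <- level_stats(y, idx, as.character(xi), sq)
    vals <- stats$levels
    ord <- seq_along(vals)
  }
  n_l <- length(vals)
  if (n_l < 2) return(NULL)
  heuristic <- FALSE
  if (ordered_pred || n_l > 15) {
    if (!ordered_pred) {
      # Too many levels for exhaustive search: order level centroids along
      # their first principal axis and split as if ordered.
      heuristic <- TRUE
      centro <- stats$gram / outer(stats$n, stats$n) # centroid inner products
      cc <- gower_centre(centro)
      ord <- order(eigen(cc, symmetric = TRUE)$vectors[, 1])
    }
    best <- NULL
    for (k in seq_len(n_l - 1)) {
      sel <- seq_len(n_l) %in% ord[seq_len(k)]
      ss <- subset_ss(stats, sel)
      if (is.null(best) || ss < best$ss) best <- list(sel = sel, ss = ss)
    }
  } else {
    best <- NULL
    for (code in seq_len(2^(n_l - 1) - 1)) {
      sel <- as.logical(bitwAnd(code, 2^(seq_len(n_l) - 1)))
      ss <- subset_ss(stats, sel)
      if (is.null(best) || ss < best$ss) best <- list(sel = sel, ss = ss)
    }
  }
  sel_levels <- vals[best$sel]
  if (ordered_pred) {
    cut <- (max(sel_levels) + min(vals[!best$sel])) / 2
    in_left <- as.numeric(xi) <= cut
    rule <- sprintf("%s <= %g", name, cut)
    type <- "ordered"
  } else {
    in_left <- as.character(xi) %in% sel_levels
    rule <- sprintf("%s in {%s}", name, paste(sel_levels, collapse = ","))
    type <- "categorical"
    cut <- NA_real_
  }
  list(predictor = name, type = type, cut = cut, rule = rule,
       left = idx[in_left], right = idx[!in_left], ss = best$ss,
       heuristic = heuristic)
}

best_split <- function(y, idx, predictors, sq) {
  cands <- purrr::compact(purrr::imap(predictors, function(x, nm) {
    best_split_one(y, idx, x, nm, sq)
  }))
  if (!length(cands)) return(NULL)
  cands[[which.min(purrr::map_dbl(cands, "ss"))]]
}

# Permutation p-value of a node's best split: permute the node's response rows
# (breaking the response-predictor link), re-find the best split each time.
split_p_value <- function(y, idx, predictors, observed_reduction, n_perm, sq) {
  if (n_perm <= 0) return(NA_real_)
  parent <- node_ss(y, idx, sq)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    idx_perm <- sample(idx)
    y_b <- y
    y_b[idx, ] <- y[idx_perm, , drop = FALSE]
    sq_b <- sq
    sq_b[idx] <- sq[idx_perm]
    cand <- best_split(y_b, idx, predictors, sq_b)
    red_b <- if (is.null(cand)) 0 else parent - cand$ss
    exceed <- exceed + (red_b >= observed_reduction)
  }
  (exceed + 1) / (n_perm + 1)
}

#' Fit a multivariate regression tree
#'
#' Greedy binary partitioning of a multivariate response driven by categorical
#' (e.g. site) and ordered (e.g. time) predictors. Ordered predictors split at
#' value boundaries; categorical predictors with at most 15 observed levels
#' are searched exhaustively over binary level partitions (beyond that, levels
#' are ordered by the first principal axis of their centroids and treated as
#' ordered, flagged in the output). Each candidate split must pass a
#' permutation test of its variance reduction at `alpha`; the tree stops at
#' `max_leaves` or at the first non-significant split.
#'
#' @param response Numeric matrix (rows = observations), e.g. square-root
#'   transformed quantities or PCoA coordinates.
#' @param predictors Data frame of predictors aligned with rows.
#' @param max_leaves Maximum number of leaves.
#' @param alpha Significance level for accepting a split.
#' @param n_perm Permutations per split test (0 disables testing).
#' @param seed Optional integer seed.
#' @return An object of class `split_tree`: `splits` (tibble: node, rule,
#'   predictor, r_squared_gain, cumulative_r_squared, p_value), `leaves`
#'   (integer leaf label per observation), `ss_total`, `r_squared`.
#' @examples
#' y <- rbind(matrix(0, 6, 3), matrix(5, 6, 3)) + rnorm(36, sd = 0.1)
#' mrt_fit(y, data.frame(time = rep(1:6, each = 2)), n_perm = 99, seed = 1)
#' @export
mrt_fit <- function(response, predictors, max_leaves = 8, alpha = 0.05,
                    n_perm = 999, seed = NULL) {
  y <- as.matrix(response)
  predictors <- as.data.frame(predictors)
  if (nrow(y) != nrow(predictors)) abort("Predictors must align with response rows.")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(y)
  sq <- rowSums(y^2)
  ss_total <- node_ss(y, seq_len(n), sq)
  leaves <- list(seq_len(n))
  splits <- list()
  if (ss_total > 0) {
    repeat {
      if (length(leaves) >= max_leaves) break
      cands <- purrr::map(leaves, function(idx) {
        if (length(idx) < 2) return(NULL)
        best_split(y, idx, predictors, sq)
      })
      gains <- purrr::map_dbl(seq_along(leaves), function(k) {
        if (is.null(cands[[k]])) return(-Inf)
        node_ss(y, leaves[[k]], sq) - cands[[k]]$ss
      })
      if (all(!is.finite(gains)) || max(gains) <= 0) break
      k <- which.max(gains)
      cand <- cands[[k]]
      p <- split_p_value(y, leaves[[k]], predictors, gains[k], n_perm, sq)
      if (!is.na(p) && p > alpha) break
      splits[[length(splits) + 1]] <- tibble(
        node = k, predictor = cand$predictor, rule = cand$rule,
        r_squared_gain = gains[k] / ss_total, p_value = p,
        heuristic = isTRUE(cand$heuristic)
      )
      leaves <- c(leaves[-k], list(cand$left), list(cand$right))
    }
  }
  labels <- integer(n)
  for (k in seq_along(leaves)) labels[leaves[[k]]] <- k
  splits_tbl <- dplyr::bind_rows(splits)
  if (nrow(splits_tbl)) {
    splits_tbl$cumulative_r_squared <- cumsum(splits_tbl$r_squared_gain)
  }
  r2 <- if (ss_total > 0) {
    (ss_total - sum(purrr::map_dbl(leaves, ~node_ss(y, .x, sq)))) / ss_total
  } else 0
  structure(list(splits = splits_tbl, leaves = labels, n_leaves = length(leaves),
                 ss_total = ss_total, r_squared = r2, n_perm = n_perm),
            class = "split_tree")
}

#' @export
print.split_tree <- function(x, ...) {
  cat(sprintf("<split_tree> %d leaf/leaves | R^2 = %.3f\n", x$n_leaves, x$r_squared))
  if (nrow(x$splits)) print(as.data.frame(x$splits))
  invisible(x)
}

#' @export
tidy.split_tree <- function(x, ...) x$splits

#' @export
glance.split_tree <- function(x, ...) {
  tibble(n_leaves = x$n_leaves, r_squared = x$r_squared, ss_total = x$ss_total)
}

#' Chronological split of a community time series
#'
#' Finds the best single temporally contiguous partition of the observations
#' into a pre-shift and a post-shift group: the boundary (among the
#' `n_distinct - 1` chronological boundaries) minimising the within-group sum
#' of squares. The explained variance `R^2` equals the RDA R-squared of the
#' induced two-level factor, and its significance is assessed by permuting the
#' response rows and re-optimising the boundary each time.
#'
#' @param response Numeric matrix (rows = observations).
#' @param time Numeric time values aligned with rows.
#' @param n_perm Number of permutations (0 skips the test).
#' @param seed Optional integer seed.
#' @return An object of class `chrono_split`: `boundary` (midpoint time),
#'   `groups` (factor `"pre"`/`"post"` per observation), `r_squared`,
#'   `p_value`, `n_perm`.
#' @export
chronological_split <- function(response, time, n_perm = 999, seed = NULL) {
  y <- as.matrix(response)
  if (nrow(y) != length(time)) abort("`time` must align with response rows.")
  t_vals <- sort(unique(time))
  if (length(t_vals) < 2) abort("Need at least 2 distinct time values.")
  n <- nrow(y)
  sq <- rowSums(y^2)
  ss_tot <- node_ss(y, seq_len(n), sq)
  if (ss_tot <= 0) {
    cut <- (t_vals[1] + t_vals[2]) / 2
    return(structure(list(boundary = cut,
                          groups = factor(ifelse(time <= cut, "pre", "post"),
                                          levels = c("pre", "post")),
                          r_squared = 0, p_value = NA_real_, n_perm = n_perm),
                     class = "chrono_split"))
  }
  best_of <- function(stats) {
    # stats over the chronological level order; scan all boundaries
    best <- c(r2 = -Inf, k = NA_real_)
    for (k in seq_len(length(stats$n) - 1)) {
      sel <- seq_along(stats$n) <= k
      r2 <- 1 - subset_ss(stats, sel) / ss_tot
      if (r2 > best[["r2"]]) best <- c(r2 = r2, k = k)
    }
    best
  }
  idx <- seq_len(n)
  obs <- best_of(level_stats(y, idx, time, sq))
  boundary <- (t_vals[obs[["k"]]] + t_vals[obs[["k"]] + 1]) / 2
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      stats_b <- list()
      f <- factor(time)
      s <- rowsum(y[perm, , drop = FALSE], f)
      stats_b <- list(levels = levels(f), n = as.vector(table(f)),
                      q = as.vector(rowsum(sq[perm], f)), gram = tcrossprod(s))
      exceed <- exceed + (best_of(stats_b)[["r2"]] >= obs[["r2"]])
    }
    p <- (exceed + 1) / (n_perm + 1)
  }
  structure(
    list(boundary = boundary,
         groups = factor(ifelse(time <= boundary, "pre", "post"),
                         levels = c("pre", "post")),
         r_squared = unname(obs[["r2"]]), p_value = p, n_perm = n_perm),
    class = "chrono_split"
  )
}

#' @export
print.chrono_split <- function(x, ...) {
  cat(sprintf("<chrono_split> boundary at %g | R^2 = %.3f | p = %s (%d perms)\n",
              x$boundary, x$r_squared, format(x$p_value, digits = 3), x$n_perm))
  invisible(x)
}

#' @export
glance.chrono_split <- function(x, ...) {
  tibble(boundary = x$boundary, r_squared = x$r_squared,
         p_value = x$p_value, n_perm = x$n_perm,
         n_pre = sum(x$groups == "pre"), n_post = sum(x$groups == "post"))
}
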