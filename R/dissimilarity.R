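# Percentage-difference dissimilarity and its replacement / abundance-difference
# decomposition.
#
# For two observations with quantity vectors y1, y2:
#   A = sum_j min(y1j, y2j)   shared quantity
#   B = sum_j (y1j - min)     surplus of observation 1
#   C = sum_j (y2j - min)     surplus of observation 2
#   d      = (B + C) / (2A + B + C)        percentage difference (Bray-Curtis)
#   repl   = 2 min(B, C) / (2A + B + C)    reciprocal replacement
#   diff   = |B - C| / (2A + B + C)        net abundance difference
# so that d = repl + diff exactly. All matrix-level quantities are computed
# from row totals and the Manhattan distance (A = (S_i + S_j - L1_ij)/2),
# which keeps the pairwise pass at C speed.

#' Shared and surplus quantity components of an observation pair
#'
#' @param y1,y2 Non-negative numeric vectors of equal length (one entry per
#'   species).
#' @return A named list with components `A` (shared quantity), `B` (surplus of
#'   `y1`) and `C` (surplus of `y2`); `A + B` and `A + C` are the two totals.
#' @examples
#' abc(c(4, 1, 0), c(1, 1, 3)) # A = 2, B = 3, C = 3
#' @export
abc <- function(y1, y2) {
  check_pair(y1, y2)
  m <- pmin(y1, y2)
  list(A = sum(m), B = sum(y1 - m), C = sum(y2 - m))
}

check_pair <- function(y1, y2) {
  if (length(y1) != length(y2)) {
    abort(sprintf("Vector lengths differ (%d vs %d).", length(y1), length(y2)))
  }
  if (anyNA(y1) || anyNA(y2)) abort("Quantity vectors must not contain NA.")
  if (any(y1 < 0) || any(y2 < 0)) abort("Quantities must be non-negative.")
  invisible(NULL)
}

#' Percentage-difference (Bray-Curtis) dissimilarity of a pair
#'
#' Equals `(B + C) / (2A + B + C)`, equivalently
#' `sum(|y1 - y2|) / sum(y1 + y2)`: 0 for identical observations, 1 for
#' disjoint supports. If both observations are entirely zero the pair is
#' treated as identical (d = 0).
#'
#' @inheritParams abc
#' @return A dissimilarity in \[0, 1\].
#' @examples
#' percentage_difference(c(4, 1, 0), c(1, 1, 3)) # 0.6
#' @export
percentage_difference <- function(y1, y2) {
  comp <- abc(y1, y2)
  denom <- 2 * comp$A + comp$B + comp$C
  if (denom == 0) return(0)
  (comp$B + comp$C) / denom
}

#' Decompose a pair's dissimilarity into replacement and abundance difference
#'
#' `repl = 2 min(B, C) / (2A + B + C)` captures reciprocal quantity exchange
#' among species; `diff = |B - C| / (2A + B + C)` captures the net difference
#' in total quantity. Their sum is exactly [percentage_difference()]. A pair
#' with one empty observation is pure abundance difference (`repl = 0`,
#' `diff = 1`); a both-empty pair returns `(0, 0)`.
#'
#' @inheritParams abc
#' @return A named list with `repl` and `diff`.
#' @examples
#' decompose_pair(c(2, 0), c(0, 1)) # repl = 2/3, diff = 1/3
#' @export
decompose_pair <- function(y1, y2) {
  comp <- abc(y1, y2)
  denom <- 2 * comp$A + comp$B + comp$C
  if (denom == 0) return(list(repl = 0, diff = 0))
  list(repl = 2 * min(comp$B, comp$C) / denom,
       diff = abs(comp$B - comp$C) / denom)
}

#' Pairwise decomposed dissimilarity matrices
#'
#' Computes, over all observation pairs of a community table, the
#' percentage-difference dissimilarity and its additive decomposition. The
#' three square symmetric matrices satisfy `D_total = D_repl + D_diff`
#' elementwise (to machine precision) with zero diagonals.
#'
#' @param table A [community_table()], or a plain numeric matrix / data frame
#'   of non-negative quantities (rows = observations).
#' @return An object of class `decomposed_dissim`: a list with matrices
#'   `D_total`, `D_repl`, `D_diff` and the observation ids.
#' @examples
#' m <- rbind(a = c(4, 1, 0), b = c(1, 1, 3), c = c(0, 0, 3))
#' decompose_matrix(m)$D_total
#' @export
decompose_matrix <- function(table) {
  values <- community_values(table)
  n <- nrow(values)
  if (n < 2) abort("Need at least 2 observations.")
  s <- rowSums(values)
  l1 <- as.matrix(dist(values, method = "manhattan"))
  ssum <- outer(s, s, "+")      # 2A + B + C
  sdif <- abs(outer(s, s, "-")) # |B - C|
  denom <- ifelse(ssum == 0, 1, ssum) # both-empty pairs -> d = 0 by convention
  d_total <- l1 / denom
  d_diff <- sdif / denom
  d_repl <- d_total - d_diff # 2*min(B,C) = (B+C) - |B-C|
  d_repl[d_repl < 0] <- 0    # guard tiny negative round-off
  diag(d_total) <- diag(d_repl) <- diag(d_diff) <- 0
  ids <- rownames(values) %||% as.character(seq_len(n))
  dimnames(d_total) <- dimnames(d_repl) <- dimnames(d_diff) <- list(ids, ids)
  structure(list(D_total = d_total, D_repl = d_repl, D_diff = d_diff, obs_id = ids),
            class = "decomposed_dissim")
}

community_values <- function(table) {
  if (inherits(table, "community_table")) return(table$values)
  if (is.data.frame(table)) {
    if (is.character(table[[1]]) || is.factor(table[[1]])) {
      values <- as.matrix(table[, -1, drop = FALSE])
      rownames(values) <- as.character(table[[1]])
      return(values)
    }
    return(as.matrix(table))
  }
  as.matrix(table)
}

#' @export
print.decomposed_dissim <- function(x, ...) {
  cat(sprintf("<decomposed_dissim> %d observations; mean d_total = %.3f (repl %.3f + diff %.3f)\n",
              nrow(x$D_total), mean(lower_tri(x$D_total)),
              mean(lower_tri(x$D_repl)), mean(lower_tri(x$D_diff))))
  invisible(x)
}

lower_tri <- function(m) m[lower.tri(m)]

#' Long-format pair table of a decomposition
#'
#' @param x A `decomposed_dissim`.
#' @param ... Unused.
#' @return A tibble `obs_i, obs_j, d_total, d_repl, d_diff`, one row per
#'   unordered observation pair.
#' @export
tidy.decomposed_dissim <- function(x, ...) {
  idx <- which(lower.tri(x$D_total), arr.ind = TRUE)
  tibble(
    obs_i = x$obs_id[idx[, 2]],
    obs_j = x$obs_id[idx[, 1]],
    d_total = x$D_total[idx],
    d_repl = x$D_repl[idx],
    d_diff = x$D_diff[idx]
  )
}

#' Square-root embedding of a percentage-difference matrix
#'
#' The percentage-difference index is not Euclidean, but the matrix of
#' square-rooted dissimilarities is: its Gower-centred form is positive
#' semi-definite (up to numerical tolerance), so the embedded distances can be
#' represented exactly in Euclidean space for ordination and variance
#' decomposition.
#'
#' @param d_total A square symmetric dissimilarity matrix.
#' @return The elementwise square root of `d_total`.
#' @export
sqrt_embed <- function(d_total) {
  d_total <- as.matrix(d_total)
  sqrt(d_total)
}

#' Principal coordinates analysis of a distance matrix
#'
#' Gower-centres `-d^2/2`, eigen-decomposes, and returns coordinates for the
#' positive-eigenvalue axes sorted by decreasing eigenvalue. For a
#' Euclidean-embeddable input the pairwise distances among the returned
#' coordinates reproduce the input exactly. Negative eigenvalues beyond
#' tolerance trigger a warning and those axes are dropped.
#'
#' @param d A square symmetric distance matrix with zero diagonal.
#' @param tol Relative tolerance below which negative eigenvalues are treated
#'   as numerical noise (default `1e-8`).
#' @return A list with `coordinates` (rows = observations), `eigenvalues`
#'   (all, sorted descending) and `negative` (logical: any eigenvalue beyond
#'   tolerance was dropped).
#' @export
pcoa <- function(d, tol = 1e-8) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) abort("`d` must be square.")
  if (max(abs(d - t(d))) > 1e-8) abort("`d` must be symmetric.")
  g <- gower_centre(-0.5 * d^2)
  eig <- eigen(g, symmetric = TRUE)
  values <- eig$values
  scale0 <- max(abs(values), 1)
  pos <- values > tol * scale0
  negative <- any(values < -tol * scale0)
  if (negative) {
    warn(sprintf("Distance matrix is not Euclidean: %d negative eigenvalue(s) dropped (min %.3g).",
                 sum(values < -tol * scale0), min(values)))
  }
  coords <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(values[pos]), sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = values, negative = negative)
}

# Double-centre a matrix (Gower): G = (I - 11'/n) M (I - 11'/n)
gower_centre <- function(m) {
  rm <- rowMeans(m)
  cm <- colMeans(m)
  m - outer(rm, rep(1, ncol(m))) - outer(rep(1, nrow(m)), cm) + mean(m)
}
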