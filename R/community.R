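# Community tables: observations x species quantities plus aligned metadata.

#' Build a community table
#'
#' A community table couples a non-negative observations-by-species quantity
#' matrix (biomass or abundance) with per-observation metadata (site, time,
#' season, replicate and an optional habitat covariate such as percent live
#' coral cover). All downstream analyses in betashift start from this object.
#'
#' Rows are sorted deterministically by (site, time, replicate). Validation
#' enforces: no missing cells, all quantities >= 0, unique observation ids,
#' one-to-one alignment between community rows and metadata rows, and unique
#' (site, time, replicate) combinations.
#'
#' @param community A data frame whose first column is the observation id
#'   (character or factor) and whose remaining columns are species quantities.
#' @param meta A data frame with columns `obs_id`, `site`, `time`, `season`,
#'   `replicate` and optionally `coral_cover` (percent, in \[0, 100\]).
#' @return An object of class `community_table` with elements `values`
#'   (numeric matrix, rownames = obs ids), `species` (character vector) and
#'   `meta` (tibble aligned with the matrix rows).
#' @examples
#' comm <- tibble::tibble(obs_id = c("a", "b"), sp1 = c(4, 1), sp2 = c(0, 3))
#' meta <- tibble::tibble(obs_id = c("a", "b"), site = "r1", time = c(2004, 2005),
#'                        season = "wet", replicate = "t1")
#' community_table(comm, meta)
#' @export
community_table <- function(community, meta) {
  community <- as.data.frame(community, stringsAsFactors = FALSE)
  meta <- as_tibble(meta)
  if (ncol(community) < 2) {
    abort("`community` needs an id column plus at least one species column.")
  }
  obs_id <- as.character(community[[1]])
  if (anyNA(obs_id) || any(obs_id == "")) {
    abort("Missing observation ids in the community table.")
  }
  dup <- obs_id[duplicated(obs_id)]
  if (length(dup)) {
    abort(paste0("Duplicated observation id(s): ", paste(unique(dup), collapse = ", ")))
  }
  values <- as.matrix(community[, -1, drop = FALSE])
  if (!is.numeric(values)) abort("Species columns must all be numeric.")
  if (anyNA(values)) abort("Community table contains missing cells.")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    abort(sprintf("Negative quantity at observation '%s', species '%s'.",
                  obs_id[neg[1, 1]], colnames(values)[neg[1, 2]]))
  }
  rownames(values) <- obs_id

  required <- c("obs_id", "site", "time", "season", "replicate")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    abort(paste0("Metadata is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  meta$obs_id <- as.character(meta$obs_id)
  extra <- setdiff(meta$obs_id, obs_id)
  absent <- setdiff(obs_id, meta$obs_id)
  if (length(extra) || length(absent)) {
    abort(paste0(
      "Community/metadata misalignment.",
      if (length(absent)) paste0(" No metadata for: ", paste(head(absent, 5), collapse = ", "), "."),
      if (length(extra)) paste0(" Metadata without community row: ", paste(head(extra, 5), collapse = ", "), ".")
    ))
  }
  if (!is.numeric(meta$time)) abort("`meta$time` must be numeric (a real-valued time axis).")
  key <- paste(meta$site, meta$time, meta$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    abort("(site, time, replicate) combinations must be unique.")
  }
  if ("coral_cover" %in% names(meta)) {
    cc <- meta$coral_cover
    if (any(!is.na(cc) & (cc < 0 | cc > 100))) {
      abort("`coral_cover` must lie in [0, 100].")
    }
  }
  meta <- dplyr::arrange(meta, .data$site, .data$time, .data$replicate)
  values <- values[meta$obs_id, , drop = FALSE]
  structure(
    list(values = values, species = colnames(values), meta = meta),
    class = "community_table"
  )
}

#' Read a community table from CSV files
#'
#' The community file is wide CSV: first column the observation id, remaining
#' columns one per species. The metadata file is keyed by `obs_id` and carries
#' `site`, `time` (or `year`), `season`, `replicate` and optionally
#' `coral_cover`.
#'
#' @param community_path,meta_path Paths to the two CSV files.
#' @return A validated [community_table()].
#' @export
read_community <- function(community_path, meta_path) {
  community <- readr::read_csv(community_path, show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_csv(meta_path, show_col_types = FALSE, progress = FALSE)
  if (!"time" %in% names(meta) && "year" %in% names(meta)) {
    meta <- dplyr::rename(meta, time = "year")
  }
  community_table(community, meta)
}

#' Write a community table to CSV files
#'
#' Inverse of [read_community()]: writes the wide community CSV and the
#' metadata CSV. Round-trips losslessly for finite decimal inputs.
#'
#' @param table A `community_table`.
#' @param community_path,meta_path Output paths.
#' @return `table`, invisibly.
#' @export
write_community <- function(table, community_path, meta_path) {
  stopifnot(inherits(table, "community_table"))
  wide <- dplyr::bind_cols(tibble(obs_id = rownames(table$values)),
                           as_tibble(table$values))
  readr::write_csv(wide, community_path, progress = FALSE)
  readr::write_csv(table$meta, meta_path, progress = FALSE)
  invisible(table)
}

#' Transform community quantities
#'
#' Applies an elementwise transform to the quantity matrix, leaving metadata
#' untouched. The square-root transform reduces the right skew typical of
#' biomass data and compresses large values, placing component analyses
#' between raw-quantity and presence-absence behaviour; `identity` is a no-op.
#'
#' @param table A `community_table`.
#' @param transform `"sqrt"` or `"identity"`.
#' @return A transformed `community_table`.
#' @examples
#' comm <- tibble::tibble(obs_id = c("a", "b"), sp1 = c(4, 1), sp2 = c(0, 9))
#' meta <- tibble::tibble(obs_id = c("a", "b"), site = "r1", time = c(2004, 2005),
#'                        season = "wet", replicate = "t1")
#' ct <- community_table(comm, meta)
#' apply_transform(ct, "sqrt")$values
#' @export
apply_transform <- function(table, transform = c("sqrt", "identity")) {
  stopifnot(inherits(table, "community_table"))
  transform <- match.arg(transform)
  if (transform == "sqrt") table$values <- sqrt(table$values)
  table
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("<community_table> %d observations x %d species\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  sites: %d | time steps: %d | replicates per (site, time): %s\n",
              dplyr::n_distinct(x$meta$site), dplyr::n_distinct(x$meta$time),
              paste(unique(table(x$meta$site, x$meta$time)), collapse = "/")))
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$values)

#' Community table as a long tibble
#'
#' @param x A `community_table`.
#' @param ... Unused.
#' @return A tibble with one row per (observation, species) cell, joined with
#'   the observation metadata.
#' @export
as_tibble.community_table <- function(x, ...) {
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble(obs_id = rownames(x$values)), as_tibble(x$values)),
    -"obs_id", names_to = "species", values_to = "quantity"
  )
  dplyr::left_join(long, x$meta, by = "obs_id")
}
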