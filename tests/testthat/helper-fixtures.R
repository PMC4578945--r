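# Shared fixtures: the 3-observation worked example and small builders.

toy_matrix <- function() {
  rbind(a = c(4, 1, 0), b = c(1, 1, 3), c = c(0, 0, 3))
}

toy_table <- function() {
  comm <- tibble::tibble(obs_id = c("a", "b", "c"),
                         sp1 = c(4, 1, 0), sp2 = c(1, 1, 0), sp3 = c(0, 3, 3))
  meta <- tibble::tibble(obs_id = c("a", "b", "c"), site = "r1",
                         time = c(2004, 2005, 2006), season = "wet",
                         replicate = "t1")
  community_table(comm, meta)
}

random_table <- function(n_obs, n_species, seed, zero_frac = 0.3) {
  set.seed(seed)
  m <- matrix(rlnorm(n_obs * n_species), n_obs, n_species)
  m[runif(length(m)) < zero_frac] <- 0
  rownames(m) <- paste0("o", seq_len(n_obs))
  colnames(m) <- paste0("s", seq_len(n_species))
  m
}

small_config <- function(seed = 1, ...) {
  scenario_config(n_sites = 3, block_sizes = c(NE = 2, W = 1),
                  times = c(2004, 2005, 2006, 2007), n_replicates = 2,
                  n_species = 30, seed = seed, ...)
}

# Independent Gower-centring oracle (full-matrix construction).
gower_oracle <- function(d) {
  n <- nrow(d)
  one <- matrix(1 / n, n, n)
  m <- -0.5 * d
  (diag(n) - one) %*% m %*% (diag(n) - one)
}

# Independent Bray-Curtis oracle.
bray_oracle <- function(y1, y2) {
  if (sum(y1 + y2) == 0) return(0)
  sum(abs(y1 - y2)) / sum(y1 + y2)
}
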