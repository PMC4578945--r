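# Synthetic disturbance-community generator. Emulates a multi-reef biannual-
# then-annual survey: per-site logistic collapse of a habitat covariate (live
# coral cover), and a species-rich fish community whose dynamics are either
# compensatory (driver species exchange biomass so each site's expected total
# stays constant), synchronous (all species track the habitat trajectory, so
# total biomass collapses), or null (no time structure). Driver species
# identities differ between the NE and W site blocks, giving the spatial
# heterogeneity in species responses that the shift-attribution analysis is
# meant to recover.

stream_seed <- function(seed, k) (abs(seed) + k * 1000003L) %% .Machine$integer.max

#' Scenario configuration for the synthetic community generator
#'
#' Defaults reproduce the survey geometry of a 13-reef monitoring design:
#' 9 north-eastern and 4 western reefs, 14 time steps (biannual wet/dry
#' surveys 2004-2009, then annual 2010-2012), 3 transect replicates, and 227
#' species. Habitat (percent live coral cover) collapses logistically on each
#' site with pre-disturbance level ~ U(32, 59)%, post level ~ U(1, 7)%,
#' inflection time ~ U(2007, 2009) and scale ~ U(0.3, 0.8) years. Each site
#' block has 7 driver species (4 increasers, 3 decreasers by default) whose
#' expected biomass tracks the habitat collapse; remaining species are stable
#' background. Observation noise is mean-preserving lognormal (sd 0.6 on the
#' log scale) with per-species occupancy thinning, plus a small additive
#' dry-season effect.
#'
#' @param n_sites Number of sites (split into blocks by `block_sizes`).
#' @param block_sizes Named integer vector of sites per block (sums to
#'   `n_sites`).
#' @param times Numeric survey times.
#' @param n_replicates Transects per site and time.
#' @param n_species Number of species.
#' @param regime `"compensatory"`, `"synchronous"` or `"null"`.
#' @param n_drivers Driver species per block.
#' @param driver_directions Signs (+1 increase, -1 decrease) of the drivers.
#' @param noise_sd Lognormal sd of observation noise (log scale).
#' @param season_effect Additive dry-season effect as a fraction of baseline.
#' @param block_contrast_sd Log-scale sd of per-block species multipliers
#'   (time-constant compositional contrast between site blocks).
#' @param occupancy_range Occupancy probability range for background species.
#' @param driver_occupancy Occupancy probability of driver species.
#' @param cover_start,cover_end,inflection,inflection_scale Ranges (length-2)
#'   for the per-site habitat logistic parameters.
#' @param seed Integer seed; all randomness (parameter draws, habitat
#'   sampling, community noise) flows from it through named streams.
#' @return A `scenario_config` list, including the realised per-site habitat
#'   parameter table `habitat` and the driver species table `drivers`.
#' @export
scenario_config <- function(n_sites = 13,
                            block_sizes = c(NE = 9, W = 4),
                            times = c(seq(2004, 2009, by = 0.5), 2010, 2011, 2012),
                            n_replicates = 3,
                            n_species = 227,
                            regime = c("compensatory", "synchronous", "null"),
                            n_drivers = 7,
                            driver_directions = c(1, 1, 1, 1, -1, -1, -1),
                            noise_sd = 0.6,
                            season_effect = 0.05,
                            block_contrast_sd = 0.6,
                            occupancy_range = c(0.3, 0.95),
                            driver_occupancy = 0.98,
                            cover_start = c(32, 59),
                            cover_end = c(1, 7),
                            inflection = c(2007, 2009),
                            inflection_scale = c(0.3, 0.8),
                            seed = 1L) {
  regime <- match.arg(regime)
  if (sum(block_sizes) != n_sites) abort("`block_sizes` must sum to `n_sites`.")
  if (length(driver_directions) != n_drivers) {
    abort("`driver_directions` must have length `n_drivers`.")
  }
  n_blocks <- length(block_sizes)
  if (n_blocks * n_drivers * 2 > n_species) {
    abort("Not enough species for the requested driver structure.")
  }
  sites <- sprintf("r%02d", seq_len(n_sites))
  blocks <- rep(names(block_sizes), block_sizes)
  set.seed(stream_seed(seed, 1L)) # parameter stream
  habitat <- tibble(
    site = sites, block = blocks,
    Y_b = runif(n_sites, cover_start[1], cover_start[2]),
    Y_a = runif(n_sites, cover_end[1], cover_end[2]),
    T = runif(n_sites, inflection[1], inflection[2]),
    sigma = runif(n_sites, inflection_scale[1], inflection_scale[2])
  )
  species <- sprintf("sp%03d", seq_len(n_species))
  # Block-specific driver species: disjoint id sets per block.
  drivers <- purrr::imap_dfr(seq_len(n_blocks), function(b, i) {
    idx <- (b - 1) * n_drivers + seq_len(n_drivers)
    tibble(block = names(block_sizes)[b], species = species[idx],
           direction = driver_directions)
  })
  # Background species: right-skewed baseline biomass. Driver decreasers are
  # initially dominant (disturbance-sensitive habitat specialists); driver
  # increasers start subordinate and are released by the disturbance.
  baseline <- rlnorm(n_species, meanlog = log(2), sdlog = 1)
  dec_ids <- drivers$species[drivers$direction < 0]
  inc_ids <- drivers$species[drivers$direction > 0]
  baseline[match(dec_ids, species)] <- rlnorm(length(dec_ids),
                                              meanlog = log(45), sdlog = 0.2)
  baseline[match(inc_ids, species)] <- rlnorm(length(inc_ids),
                                              meanlog = log(10), sdlog = 0.2)
  occupancy <- runif(n_species, occupancy_range[1], occupancy_range[2])
  occupancy[match(drivers$species, species)] <- driver_occupancy
  # Time-constant compositional contrast between blocks: mean-preserving
  # lognormal multipliers per (block, species).
  block_mult <- matrix(rlnorm(n_blocks * n_species,
                              meanlog = -block_contrast_sd^2 / 2,
                              sdlog = block_contrast_sd),
                       n_blocks, n_species,
                       dimnames = list(names(block_sizes), species))
  structure(
    list(n_sites = n_sites, sites = sites, blocks = blocks,
         block_sizes = block_sizes, times = times,
         n_replicates = n_replicates, n_species = n_species, species = species,
         regime = regime, drivers = drivers, baseline = baseline,
         block_mult = block_mult, occupancy = occupancy, noise_sd = noise_sd,
         season_effect = season_effect, habitat = habitat, seed = seed),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %d sites (%s) x %d times x %d replicates | %d species | regime: %s | seed %d\n",
              x$n_sites, paste(sprintf("%s:%d", names(x$block_sizes), x$block_sizes), collapse = ", "),
              length(x$times), x$n_replicates, x$n_species, x$regime, x$seed))
  invisible(x)
}

obs_grid <- function(config) {
  grid <- tidyr::expand_grid(site = config$sites, time = config$times,
                             replicate = sprintf("t%d", seq_len(config$n_replicates)))
  dplyr::mutate(grid,
                season = ifelse(grid$time %% 1 == 0, "wet", "dry"),
                obs_id = sprintf("%s_%06.1f_%s", grid$site, grid$time, grid$replicate))
}

#' Simulate the habitat covariate (percent live coral cover)
#'
#' The expected cover at each site follows its logistic collapse; the observed
#' per-transect cover emulates the point-intercept sampling protocol:
#' `100 * Binomial(50, expected/100) / 50`.
#'
#' @param config A [scenario_config()].
#' @return A tibble `obs_id, site, time, season, replicate, expected_cover,
#'   coral_cover`.
#' @export
simulate_habitat <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  grid <- obs_grid(config)
  hp <- config$habitat[match(grid$site, config$habitat$site), ]
  expected <- logistic_curve(grid$time, hp$Y_b, hp$Y_a, hp$T, hp$sigma)
  set.seed(stream_seed(config$seed, 2L)) # habitat stream
  observed <- 100 * rbinom(nrow(grid), 50, expected / 100) / 50
  dplyr::bind_cols(grid[, c("obs_id", "site", "time", "season", "replicate")],
                   tibble(expected_cover = expected, coral_cover = observed))
}

# Expected biomass matrix (times x species) for one site under the regime.
site_expected <- function(config, site) {
  hp <- config$habitat[config$habitat$site == site, ]
  block <- config$blocks[match(site, config$sites)]
  h <- logistic_curve(config$times, hp$Y_b, hp$Y_a, hp$T, hp$sigma)
  h_rel <- h / h[1]
  b <- config$baseline * config$block_mult[block, ]
  n_t <- length(config$times)
  e <- matrix(b, nrow = n_t, ncol = config$n_species, byrow = TRUE,
              dimnames = list(NULL, config$species))
  if (config$regime == "null") return(e)
  if (config$regime == "synchronous") return(e * h_rel)
  # compensatory: block drivers exchange biomass; site total expected constant
  dr <- config$drivers[config$drivers$block == block, ]
  dec <- dr$species[dr$direction < 0]
  inc <- dr$species[dr$direction > 0]
  b_dec <- b[match(dec, config$species)]
  b_inc <- b[match(inc, config$species)]
  e[, dec] <- outer(h_rel, b_dec)
  loss <- (1 - h_rel) * sum(b_dec)
  w <- b_inc / sum(b_inc)
  e[, inc] <- matrix(b_inc, n_t, length(inc), byrow = TRUE) + outer(loss, w)
  e
}

#' Simulate a disturbance-driven community table
#'
#' Builds the full observations-by-species biomass table for the configured
#' design: per-site expected trajectories under the regime, an additive
#' dry-season effect, mean-preserving lognormal observation noise, and
#' per-species occupancy thinning (zero inflation). Metadata carries the
#' simulated coral cover.
#'
#' @param config A [scenario_config()].
#' @return A [community_table()].
#' @examples
#' ct <- simulate_community(scenario_config(n_sites = 3, n_species = 30, seed = 7))
#' dim(ct)
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  habitat <- simulate_habitat(config)
  expected_site <- lapply(config$sites, function(s) site_expected(config, s))
  names(expected_site) <- config$sites
  grid <- obs_grid(config)
  t_index <- match(grid$time, config$times)
  e_obs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    expected_site[[grid$site[i]]][t_index[i], ]
  }))
  dry <- grid$season == "dry"
  if (any(dry)) {
    e_obs[dry, ] <- e_obs[dry, , drop = FALSE] +
      matrix(config$season_effect * config$baseline, sum(dry), config$n_species,
             byrow = TRUE)
  }
  set.seed(stream_seed(config$seed, 3L)) # community noise stream
  n_cells <- length(e_obs)
  noise <- matrix(rlnorm(n_cells, meanlog = -config$noise_sd^2 / 2,
                         sdlog = config$noise_sd),
                  nrow(e_obs), ncol(e_obs))
  present <- matrix(rbinom(n_cells, 1, rep(config$occupancy, each = nrow(e_obs))),
                    nrow(e_obs), ncol(e_obs))
  values <- e_obs * noise * present
  community <- dplyr::bind_cols(tibble(obs_id = grid$obs_id),
                                as_tibble(values))
  meta <- dplyr::select(
    dplyr::left_join(grid, habitat[, c("obs_id", "coral_cover")], by = "obs_id"),
    "obs_id", "site", "time", "season", "replicate", "coral_cover"
  )
  community_table(community, meta)
}

#' Paper-scale synthetic preset
#'
#' A fixed study design at full survey scale: 546 observations (13 sites x 14
#' time steps x 3 replicates) by 227 species, with sharp block-specific shift
#' times — the 9 NE sites collapse around 2006.75 (a 2007 shift) and the 4 W
#' sites around 2009.5 (a 2010 shift) — and 7 driver species per block. Used
#' for end-to-end validation of the whole pipeline.
#'
#' @param seed Integer seed.
#' @param regime Community regime (default compensatory).
#' @return A list with `table` (the [community_table()]) and `config`. The
#'   config carries `shift_boundaries`, the programmed chronological
#'   boundaries per block.
#' @export
preset_paper_scale <- function(seed = 1L, regime = "compensatory") {
  config <- scenario_config(regime = regime, seed = seed)
  ne <- config$habitat$block == "NE"
  config$habitat$T[ne] <- 2006.75
  config$habitat$T[!ne] <- 2009.5
  config$habitat$sigma[] <- 0.1
  config$shift_boundaries <- c(NE = 2006.75, W = 2009.5)
  list(table = simulate_community(config), config = config)
}
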