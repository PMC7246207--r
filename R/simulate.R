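# Synthetic landscapes, fire histories and visitation surveys with the
# statistical structure the downstream analysis assumes: a pyrodiversity ->
# richness gradient, a drought year that thins blooms but not plant richness,
# and pollinator-specific partner flexibility that interacts with
# pyrodiversity to set abundance change between years.

#' Simulation parameters
#'
#' Defaults emulate the field design the package targets: 18 monitoring sites
#' sampled 4 times per year in two consecutive drought years (a "severe" and
#' an "extreme" year), on a 30 m landscape grid carrying a handful of
#' overlapping mixed-severity fires.
#'
#' @param n_sites number of monitoring sites.
#' @param n_rounds_per_year survey rounds per year.
#' @param years character pair naming the severe- and extreme-drought years.
#' @param grid_size landscape grid cells per side.
#' @param cell_size_m raster cell edge (m).
#' @param n_fires number of fires in the record.
#' @param n_severity_classes within-fire severity categories.
#' @param n_plants,n_pollinators species-pool sizes.
#' @param richness_slope expected extra species (per trophic level) per unit
#'   pyrodiversity.
#' @param drought_bloom_factor multiplicative bloom reduction in the extreme
#'   year, in (0, 1].
#' @param flexibility_dist function(n) drawing per-pollinator partner-switching
#'   propensities on \[0, 1\].
#' @param beta_interaction true coefficient of pyrodiversity x centered
#'   flexibility on the between-year log-ratio of pollinator abundance.
#' @param noise_sd residual SD of the species-by-site log-ratio.
#' @param base_occupancy baseline per-species site-occupancy probability at
#'   pyrodiversity 0.
#' @param visit_rate mean visits per pollinator per site-year when present.
#' @param bloom_rate mean blooms per plant per site-round when present.
#' @param pref_conc preference sharpness: larger values concentrate an
#'   inflexible pollinator's visits on its favourite plants.
#' @param seed integer master seed; every sub-generator derives its stream
#'   from it (see Details).
#' @details One master seed governs all stages via fixed offsets
#'   (`seed*1000 + stage`), so each stage is independently reproducible.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_sites = 18, n_rounds_per_year = 4,
                       years = c(severe = "2013", extreme = "2014"),
                       grid_size = 60, cell_size_m = 30,
                       n_fires = 3, n_severity_classes = 4,
                       n_plants = 20, n_pollinators = 30,
                       richness_slope = 6, drought_bloom_factor = 0.5,
                       flexibility_dist = function(n) stats::rbeta(n, 2, 2),
                       beta_interaction = 1.5, noise_sd = 0.3,
                       base_occupancy = 0.45, visit_rate = 30,
                       bloom_rate = 40, pref_conc = 8, seed = 1) {
  p <- list(n_sites = n_sites, n_rounds_per_year = n_rounds_per_year,
            years = years, grid_size = grid_size, cell_size_m = cell_size_m,
            n_fires = n_fires, n_severity_classes = n_severity_classes,
            n_plants = n_plants, n_pollinators = n_pollinators,
            richness_slope = richness_slope,
            drought_bloom_factor = drought_bloom_factor,
            flexibility_dist = flexibility_dist,
            beta_interaction = beta_interaction, noise_sd = noise_sd,
            base_occupancy = base_occupancy, visit_rate = visit_rate,
            bloom_rate = bloom_rate, pref_conc = pref_conc,
            seed = as.integer(seed))
  counts <- c("n_sites", "n_rounds_per_year", "grid_size", "n_severity_classes",
              "n_plants", "n_pollinators")
  for (k in counts) if (p[[k]] < 1) stop(k, " must be >= 1")
  if (p$n_fires < 0) stop("n_fires must be >= 0")
  if (drought_bloom_factor <= 0 || drought_bloom_factor > 1)
    stop("drought_bloom_factor must be in (0, 1]")
  if (length(years) != 2) stop("years must name exactly two years")
  if (grid_size * cell_size_m < 2 * 150 + cell_size_m)
    stop("grid too small to contain a site buffer")
  class(p) <- "sim_params"
  p
}

# stage-specific RNG streams off the one master seed
.sim_seed <- function(params, stage) {
  set.seed((params$seed %% 1000000L) * 1000L + stage)
}

#' Generate per-fire burn-severity rasters
#'
#' Each fire burns a set of random circular patches ("blobs"); severity within
#' a fire is the class of the nearest covering blob centre, giving spatially
#' autocorrelated mosaics whose overlaps create distinct fire histories.
#'
#' @param params a [sim_params()].
#' @return a [fire_raster_stack()] with `n_fires` layers (possibly zero).
#' @export
gen_fire_rasters <- function(params) {
  .sim_seed(params, 1L)
  n <- params$grid_size
  cs <- params$cell_size_m
  extent <- n * cs
  coords_x <- (rep(seq_len(n), each = n) - 0.5) * cs   # col-major: x by column
  coords_y <- (n - rep(seq_len(n), times = n) + 0.5) * cs
  layers <- vector("list", params$n_fires)
  for (f in seq_len(params$n_fires)) {
    n_blobs <- sample(3:6, 1)
    bx <- stats::runif(n_blobs, 0, extent)
    by <- stats::runif(n_blobs, 0, extent)
    br <- stats::runif(n_blobs, extent / 6, extent / 2.5)
    bsev <- sample.int(params$n_severity_classes, n_blobs, replace = TRUE)
    lay <- rep(NA_real_, n * n)
    # nearest covering blob decides severity
    best <- rep(Inf, n * n)
    for (b in seq_len(n_blobs)) {
      d <- sqrt((coords_x - bx[b])^2 + (coords_y - by[b])^2)
      hit <- d <= br[b] & d < best
      lay[hit] <- bsev[b]
      best[hit] <- d[hit]
    }
    layers[[f]] <- matrix(lay, nrow = n, ncol = n)
  }
  fire_raster_stack(layers, xll = 0, yll = 0, cell_size_m = cs,
                    severity_classes = params$n_severity_classes)
}

#' Generate monitoring-site locations
#'
#' Sites are placed uniformly at random, inset so a 150 m buffer fits inside
#' the landscape grid.
#'
#' @param params a [sim_params()].
#' @param radius_m buffer radius that must fit within the grid.
#' @return data.frame with columns `site`, `x`, `y`.
#' @export
gen_sites <- function(params, radius_m = 150) {
  .sim_seed(params, 2L)
  extent <- params$grid_size * params$cell_size_m
  if (extent <= 2 * radius_m) stop("grid too small to contain any site buffer")
  data.frame(site = sprintf("site_%02d", seq_len(params$n_sites)),
             x = stats::runif(params$n_sites, radius_m, extent - radius_m),
             y = stats::runif(params$n_sites, radius_m, extent - radius_m),
             stringsAsFactors = FALSE)
}

#' Generate visitation and floral-survey tables
#'
#' For each site the local plant and pollinator pools are drawn once (so plant
#' richness is preserved across years in expectation and realisation), with
#' occupancy probability increasing in pyrodiversity so expected richness
#' rises by `richness_slope` species per unit score. Bloom counts are shifted
#' Poisson (every present plant keeps at least one bloom), scaled by
#' `drought_bloom_factor` in the extreme year. Each pollinator's visits are
#' Poisson in total, with the extreme-year rate multiplied by
#' `exp(beta_interaction * pyrodiversity * (flexibility - mean) + noise)`, and
#' are allocated to plants by a log-linear mixture of a fixed species
#' preference profile (weight `1 - flexibility`, sharpened by `pref_conc`) and
#' the local bloom abundances (weight `flexibility`) — so flexible species
#' track local resources while inflexible ones keep their favourites. At
#' flexibility exactly 0 the allocation is the deterministic sharp limit: all
#' visits go to the highest-preference plant available.
#'
#' @param params a [sim_params()].
#' @param pyrodiv_by_site named numeric vector of pyrodiversity scores in
#'   \[0, 1\], one per site.
#' @return list with `visits` (site, year, round, plant, pollinator, count),
#'   `floral` (site, year, round, plant, count), and `species` (the generative
#'   truth: rosters, flexibility, activity, preferences).
#' @export
gen_visits <- function(params, pyrodiv_by_site) {
  if (any(pyrodiv_by_site < 0 | pyrodiv_by_site > 1))
    stop("pyrodiversity scores must be in [0, 1]")
  .sim_seed(params, 3L)
  sites <- names(pyrodiv_by_site)
  if (is.null(sites)) {
    sites <- sprintf("site_%02d", seq_along(pyrodiv_by_site))
    names(pyrodiv_by_site) <- sites
  }
  plants <- sprintf("plant_%02d", seq_len(params$n_plants))
  polls <- sprintf("bee_%02d", seq_len(params$n_pollinators))
  years <- unname(params$years)
  rounds <- seq_len(params$n_rounds_per_year)

  flex <- params$flexibility_dist(params$n_pollinators)
  flex <- pmin(pmax(flex, 0), 1)
  names(flex) <- polls
  flex_c <- flex - mean(flex)
  activity <- stats::rlnorm(params$n_pollinators, log(params$visit_rate), 0.4)
  bloom_base <- stats::rlnorm(params$n_plants, log(params$bloom_rate), 0.4)
  # per-pollinator plant preference profiles (skewed, Dirichlet-like)
  pref <- matrix(stats::rgamma(params$n_pollinators * params$n_plants, 0.5),
                 nrow = params$n_pollinators,
                 dimnames = list(polls, plants))
  pref <- pref / rowSums(pref)

  # occupancy: E[richness] = n * base_occupancy + richness_slope * pyrodiv
  occ_p <- function(n_species, pyro)
    pmin(pmax(params$base_occupancy + params$richness_slope * pyro / n_species,
              0.02), 1)
  plant_pool <- lapply(sites, function(s)
    plants[stats::runif(params$n_plants) < occ_p(params$n_plants, pyrodiv_by_site[s])])
  poll_pool <- lapply(sites, function(s)
    polls[stats::runif(params$n_pollinators) < occ_p(params$n_pollinators, pyrodiv_by_site[s])])
  names(plant_pool) <- names(poll_pool) <- sites

  floral_rows <- list()
  visit_rows <- list()
  for (s in sites) {
    lp <- plant_pool[[s]]
    lb <- poll_pool[[s]]
    pyro <- pyrodiv_by_site[[s]]
    # species-by-site year effect on visit rate (the generative log-ratio)
    lr <- params$beta_interaction * pyro * flex_c[lb] +
      stats::rnorm(length(lb), 0, params$noise_sd)
    names(lr) <- lb
    for (y in years) {
      yfac <- if (y == years[2]) params$drought_bloom_factor else 1
      for (r in rounds) {
        if (length(lp) == 0) next
        rmult <- stats::runif(1, 0.7, 1.3)
        lam <- pmax(bloom_base[match(lp, plants)] * rmult * yfac - 1, 0)
        blooms <- 1L + stats::rpois(length(lp), lam)
        floral_rows[[length(floral_rows) + 1L]] <-
          data.frame(site = s, year = y, round = r, plant = lp,
                     count = blooms, stringsAsFactors = FALSE)
        for (b in lb) {
          mu <- activity[match(b, polls)] / params$n_rounds_per_year
          if (y == years[2]) mu <- mu * exp(lr[[b]])
          nv <- stats::rpois(1, mu)
          if (nv == 0) next
          f <- flex[[b]]
          if (f == 0) {
            alloc <- integer(length(lp))
            alloc[which.max(pref[b, lp])] <- nv
          } else {
            w <- exp(params$pref_conc * (1 - f) * log(pref[b, lp]) +
                       f * log(blooms))
            alloc <- as.integer(stats::rmultinom(1, nv, w))
          }
          keep <- alloc > 0
          if (!any(keep)) next
          visit_rows[[length(visit_rows) + 1L]] <-
            data.frame(site = s, year = y, round = r, plant = lp[keep],
                       pollinator = b, count = alloc[keep],
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  empty_v <- data.frame(site = character(0), year = character(0),
                        round = integer(0), plant = character(0),
                        pollinator = character(0), count = integer(0),
                        stringsAsFactors = FALSE)
  empty_f <- empty_v[, c("site", "year", "round", "plant", "count")]
  visits <- if (length(visit_rows)) do.call(rbind, visit_rows) else empty_v
  floral <- if (length(floral_rows)) do.call(rbind, floral_rows) else empty_f
  if (nrow(visits) == 0)
    message("gen_visits: degenerate parameter set produced an empty visit table")
  rownames(visits) <- rownames(floral) <- NULL
  list(visits = visits, floral = floral,
       species = list(plants = plants, pollinators = polls,
                      flexibility = flex, activity = stats::setNames(activity, polls),
                      preferences = pref,
                      plant_pool = plant_pool, pollinator_pool = poll_pool,
                      pyrodiversity = pyrodiv_by_site))
}

#' Parameter-recovery table for a simulated dataset
#'
#' One row per pollinator x site present in both years: the abundance
#' log-ratio together with the generator's true pyrodiversity score and the
#' species' true flexibility, both mean-centered (`pyro_c`, `flex_c`) ready
#' for the recovery regression `log_ratio ~ pyro_c * flex_c` with a species
#' random intercept.
#'
#' @param sim the list returned by [gen_visits()] or [gen_dataset()].
#' @param params the [sim_params()] used to generate it.
#' @return data.frame: `pollinator`, `site`, `log_ratio`, `pyro`, `flex`,
#'   `pyro_c`, `flex_c`.
#' @export
resistance_truth_table <- function(sim, params) {
  years <- unname(params$years)
  combos <- unique(sim$visits[, c("site", "pollinator")])
  lr <- vapply(seq_len(nrow(combos)), function(i)
    population_log_ratio(sim$visits, combos$site[i], combos$pollinator[i],
                         years), numeric(1))
  keep <- !is.na(lr)
  tab <- data.frame(pollinator = combos$pollinator[keep],
                    site = combos$site[keep], log_ratio = lr[keep],
                    pyro = unname(sim$species$pyrodiversity[combos$site[keep]]),
                    flex = unname(sim$species$flexibility[combos$pollinator[keep]]),
                    stringsAsFactors = FALSE)
  tab$pyro_c <- tab$pyro - mean(tab$pyro)
  tab$flex_c <- tab$flex - mean(tab$flex)
  tab
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: fire rasters, site locations, pyrodiversity scores
#' from the pyrodiversity pipeline, then visitation and floral tables
#' conditioned on those scores.
#'
#' @param params a [sim_params()].
#' @param radius_m buffer radius for pyrodiversity.
#' @return list with `rasters`, `sites`, `pyrodiv` (data.frame), plus the
#'   `visits`, `floral`, `species` elements of [gen_visits()].
#' @export
gen_dataset <- function(params, radius_m = 150) {
  rasters <- gen_fire_rasters(params)
  sites <- gen_sites(params, radius_m)
  pyro <- site_pyrodiversity(rasters, sites, radius_m)
  vis <- gen_visits(params, stats::setNames(pyro$pyrodiversity, pyro$site))
  c(list(rasters = rasters, sites = sites, pyrodiv = pyro), vis)
}
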