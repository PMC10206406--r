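# Synthetic network and parameter generation: scaled-down surrogates with
# the same structural statistics as the full system (three levels, tiered
# wholesale counts in ratio 4:8:395, 5% direct-sale fractions at village
# and wholesale levels, lognormal village catchments). Everything is a
# deterministic function of the generator seed.

#' Parameters for the synthetic network generator
#'
#' Defaults are a scaled-down surrogate of a state-wide system: tier counts
#' shrink the 4:8:395 wholesale hierarchy to 1/2/10, village catchment
#' populations are lognormal with mean ~7,800 persons so that 5% direct
#' sales average ~390 consumers per village market, and each wholesale
#' market supplies 12 retailers covering 90% of its catchment's purchases.
#'
#' @param n_village Number of village markets.
#' @param n_tier1,n_tier2,n_tier3 Wholesale market counts by tier.
#' @param retailers_per_wholesale Retailers attached to each wholesale
#'   market.
#' @param bbox Bounding box `c(lat_min, lat_max, lon_min, lon_max)` within
#'   which locations are placed uniformly.
#' @param village_pop_mean Mean village catchment population.
#' @param village_pop_sigma Log-scale sigma of the lognormal catchment law.
#' @param direct_sale_fraction Share of the local catchment buying directly
#'   at village and wholesale markets.
#' @param retail_share Share of all purchases taking place at retail.
#' @param seed Generator seed.
#' @return A `generator_params` list.
#' @export
generator_params <- function(n_village = 50,
                             n_tier1 = 1, n_tier2 = 2, n_tier3 = 10,
                             retailers_per_wholesale = 12,
                             bbox = c(19.0, 22.0, 83.5, 87.0),
                             village_pop_mean = 7800,
                             village_pop_sigma = 0.8,
                             direct_sale_fraction = 0.05,
                             retail_share = 0.90,
                             seed = 1L) {
  stopifnot(n_village >= 1, n_tier1 >= 1, n_tier2 >= 0, n_tier3 >= 0,
            retailers_per_wholesale >= 1,
            direct_sale_fraction >= 0, direct_sale_fraction <= 1,
            retail_share >= 0, retail_share <= 1,
            bbox[2] > bbox[1], bbox[4] > bbox[3])
  structure(list(n_village = n_village, n_tier1 = n_tier1,
                 n_tier2 = n_tier2, n_tier3 = n_tier3,
                 retailers_per_wholesale = retailers_per_wholesale,
                 bbox = bbox, village_pop_mean = village_pop_mean,
                 village_pop_sigma = village_pop_sigma,
                 direct_sale_fraction = direct_sale_fraction,
                 retail_share = retail_share, seed = as.integer(seed)),
            class = "generator_params")
}

#' Generate a synthetic supply chain network
#'
#' Villages and wholesale markets are placed uniformly in the bounding box;
#' village catchment populations are lognormal; each wholesale market's
#' catchment is the sum of the village catchments that route to it (so both
#' the village layer and the wholesale layer cover the whole population,
#' each selling directly to its 5% share); retailers sit near their
#' wholesale market and jointly serve the retail share of that catchment.
#' Routes and the tiered partner graph come from
#' [assign_nearest_partners()]; the result always passes
#' [validate_network()], and the same seed regenerates the identical
#' network.
#'
#' @param params A [generator_params()].
#' @param ... Passed to [assign_nearest_partners()] (vehicle volumes,
#'   speeds, breakage means).
#' @return A [veg_network()].
#' @export
generate_network <- function(params, ...) {
  p <- params
  st <- rng_stream(p$seed, "network_generator")
  nw <- p$n_tier1 + p$n_tier2 + p$n_tier3
  u <- function(n, lo, hi) lo + rs_unif(st, n) * (hi - lo)

  wh_lat <- u(nw, p$bbox[1], p$bbox[2])
  wh_lon <- u(nw, p$bbox[3], p$bbox[4])
  tier <- rep(1:3, times = c(p$n_tier1, p$n_tier2, p$n_tier3))
  wh_id <- sprintf("W%03d", seq_len(nw))

  vil_lat <- u(p$n_village, p$bbox[1], p$bbox[2])
  vil_lon <- u(p$n_village, p$bbox[3], p$bbox[4])
  mu <- log(p$village_pop_mean) - p$village_pop_sigma^2 / 2
  vpop <- exp(rs_norm(st, p$n_village, mu, p$village_pop_sigma))
  vil_id <- sprintf("V%03d", seq_len(p$n_village))

  # wholesale catchment = sum of the villages that route to it
  near_wh <- vapply(seq_len(p$n_village), function(i) {
    d <- haversine_km(vil_lat[i], vil_lon[i], wh_lat, wh_lon)
    order(d, wh_id)[1]
  }, 0L)
  wpop <- vapply(seq_len(nw), function(w) sum(vpop[near_wh == w]), 0)

  loc <- list(tibble::tibble(
    id = vil_id, level = "village_market", tier = NA_integer_,
    lat = vil_lat, lon = vil_lon, population = vpop,
    direct_sale_fraction = p$direct_sale_fraction,
    storage_volume_m3 = Inf, arrival_hour = 9))
  loc[[2]] <- tibble::tibble(
    id = wh_id, level = "wholesale_market", tier = as.integer(tier),
    lat = wh_lat, lon = wh_lon, population = wpop,
    direct_sale_fraction = p$direct_sale_fraction,
    storage_volume_m3 = Inf, arrival_hour = 11)

  # retailers jittered around their wholesale market; together they serve
  # the retail share of the wholesale catchment
  nr <- p$retailers_per_wholesale
  r_w <- rep(seq_len(nw), each = nr)
  jit_lat <- rs_norm(st, nw * nr, 0, 0.05)
  jit_lon <- rs_norm(st, nw * nr, 0, 0.05)
  loc[[3]] <- tibble::tibble(
    id = sprintf("R%04d", seq_len(nw * nr)),
    level = "retailer", tier = NA_integer_,
    lat = pmin(pmax(wh_lat[r_w] + jit_lat, p$bbox[1]), p$bbox[2]),
    lon = pmin(pmax(wh_lon[r_w] + jit_lon, p$bbox[3]), p$bbox[4]),
    population = wpop[r_w] / nr,
    direct_sale_fraction = p$retail_share,
    storage_volume_m3 = Inf, arrival_hour = 12)

  locations <- dplyr::bind_rows(loc)
  net <- assign_nearest_partners(locations, ...)

  # retailers must fetch from their own wholesale market (they share its
  # catchment), not merely the geographically nearest one
  rts <- net$routes
  for (j in seq_len(nw * nr)) {
    rid <- sprintf("R%04d", j)
    rts$origin[rts$destination == rid] <- wh_id[r_w[j]]
  }
  veg_network(locations, rts, net$partners)
}

#' Default synthetic crop parameter table
#'
#' Five vegetables with synthetic default parameters anchored to printed
#' ranges: ambient lifespans potato 21 d, onion 15 d, cabbage 7 d, tomato
#' 6 d, brinjal 4 d; per-capita demands summing to 266 g/person/d; bulk
#' densities, monthly harvest profiles (potato and onion concentrated in
#' 2–3 months, tomato and brinjal near-year-round) and in-state
#' production-to-demand ratios (brinjal 5.2, potato import-dependent at
#' 0.4). Stored in `inst/extdata/default_crops_synthetic.csv` rather than
#' in code; edit a copy of that file to change the defaults.
#'
#' @return Crop tibble (passes [validate_crops()]).
#' @export
default_crops <- function() {
  path <- system.file("extdata", "default_crops_synthetic.csv",
                      package = "vegchain", mustWork = TRUE)
  read_crop_table(path)
}

#' Build the six scenario configurations of the multiplier experiment
#'
#' Baseline plus production multiplied by 1.25, 1.5, 2, 3 and 5, each with
#' a 7-day burn-in.
#'
#' @param base A [scenario_config()] supplying everything except the
#'   multiplier.
#' @return List of six `scenario_config`s.
#' @export
scenario_suite <- function(base = scenario_config()) {
  lapply(c(1, 1.25, 1.5, 2, 3, 5), function(m) {
    cfg <- base
    cfg$production_multiplier <- m
    cfg
  })
}
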