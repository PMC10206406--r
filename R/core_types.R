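#' Assemble a supply chain network from its component tables
#'
#' A network is a list of three tibbles: `locations` (market nodes),
#' `routes` (transport links with vehicle capacity and ordering policy), and
#' `partners` (undirected lateral trading edges among wholesale markets).
#' The constructor normalises column types and attaches the `veg_network`
#' class; it does not validate — use [validate_network()] for that, which
#' reports violations as data rather than throwing.
#'
#' @param locations Tibble with columns `id`, `level` (one of
#'   `"village_market"`, `"wholesale_market"`, `"retailer"`,
#'   `"surrogate_retail"`, `"external"`), `tier` (1–3 for wholesale markets,
#'   `NA` otherwise), `lat`, `lon` (degrees), `population` (catchment,
#'   persons), `direct_sale_fraction` (share of catchment buying at this
#'   node), `storage_volume_m3` (`Inf`/`NA` for unbounded) and
#'   `arrival_hour` (mean consumer arrival hour-of-day).
#' @param routes Tibble with columns `origin`, `destination` (location ids),
#'   `vehicle_m3`, `travel_h`, `depart_hour`, ordering-policy columns
#'   `quantity_mode` (`"fixed"`/`"variable"`), `frequency_mode`,
#'   `initiator` (`"supplier_delivers"`/`"recipient_fetches"`),
#'   `persistence` (`"single"`/`"persistent"`), `review_period_d`,
#'   `safety_stock_d`, `fixed_quantity_kg`, and `leg_breakage_mean`.
#' @param partners Tibble with columns `a`, `b`: undirected wholesale trading
#'   edges.
#' @return A `veg_network` object (a classed list of the three tibbles).
#' @seealso [validate_network()], [generate_network()],
#'   [assign_nearest_partners()]
#' @export
veg_network <- function(locations, routes, partners) {
  locations <- tibble::as_tibble(locations)
  routes <- tibble::as_tibble(routes)
  partners <- tibble::as_tibble(partners)
  locations$id <- as.character(locations$id)
  if (!"tier" %in% names(locations)) locations$tier <- NA_integer_
  locations$tier <- suppressWarnings(as.integer(locations$tier))
  if (!"storage_volume_m3" %in% names(locations)) {
    locations$storage_volume_m3 <- Inf
  }
  locations$storage_volume_m3[is.na(locations$storage_volume_m3)] <- Inf
  if (!"arrival_hour" %in% names(locations)) locations$arrival_hour <- 12
  if (nrow(routes)) {
    routes$origin <- as.character(routes$origin)
    routes$destination <- as.character(routes$destination)
    # an all-NA column comes back logical from read.csv
    routes$fixed_quantity_kg <- as.numeric(routes$fixed_quantity_kg)
  }
  if (nrow(partners)) {
    partners$a <- as.character(partners$a)
    partners$b <- as.character(partners$b)
  }
  structure(list(locations = locations, routes = routes, partners = partners),
            class = "veg_network")
}

#' @export
print.veg_network <- function(x, ...) {
  lv <- table(x$locations$level)
  cat("<veg_network> ", nrow(x$locations), " locations (",
      paste(names(lv), unname(lv), sep = ": ", collapse = ", "), "), ",
      nrow(x$routes), " routes, ", nrow(x$partners),
      " wholesale partner edges\n", sep = "")
  invisible(x)
}

#' Validate the structural invariants of a supply chain network
#'
#' Checks every structural rule a runnable network must satisfy: field
#' ranges on locations and routes, referential integrity, that each Tier 3
#' wholesale market has exactly one lateral trading partner, that the
#' Tier 1/2 partner subgraph is connected, and that every village market
#' ships to exactly one wholesale market and every retailer fetches from
#' exactly one wholesale market. Violations are returned as data (one row
#' each), never thrown, so the function can be used both as a gate before
#' [run_simulation()] and as a reporting tool on suspect input files.
#'
#' @param network A [veg_network()].
#' @return A tibble with columns `entity`, `rule`, `detail`; zero rows iff
#'   the network is valid.
#' @examples
#' p <- generator_params(n_village = 6, n_tier1 = 1, n_tier2 = 1, n_tier3 = 2)
#' nrow(validate_network(generate_network(p))) # 0
#' @export
validate_network <- function(network) {
  loc <- network$locations
  rts <- network$routes
  par <- network$partners
  bad <- list()
  add <- function(entity, rule, detail) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(
      entity = as.character(entity), rule = rule, detail = detail)
  }

  if (anyDuplicated(loc$id)) {
    for (d in unique(loc$id[duplicated(loc$id)]))
      add(d, "unique_id", "duplicated location id")
  }
  for (i in seq_len(nrow(loc))) {
    l <- loc[i, ]
    if (!l$level %in% LOCATION_LEVELS)
      add(l$id, "level", paste0("unknown level '", l$level, "'"))
    if (identical(l$level, "wholesale_market")) {
      if (is.na(l$tier) || !l$tier %in% 1:3)
        add(l$id, "tier", "wholesale market must carry tier 1, 2 or 3")
    } else if (!is.na(l$tier)) {
      add(l$id, "tier", "tier set on a non-wholesale location")
    }
    if (is.na(l$direct_sale_fraction) || l$direct_sale_fraction < 0 ||
        l$direct_sale_fraction > 1)
      add(l$id, "direct_sale_fraction", "must lie in [0, 1]")
    if (is.na(l$lat) || abs(l$lat) > 90)
      add(l$id, "coordinates", "latitude outside [-90, 90]")
    if (is.na(l$lon) || abs(l$lon) > 180)
      add(l$id, "coordinates", "longitude outside [-180, 180]")
    if (is.na(l$population) || l$population < 0)
      add(l$id, "population", "catchment population must be >= 0")
    if (!is.na(l$storage_volume_m3) && l$storage_volume_m3 <= 0)
      add(l$id, "storage_volume", "storage volume must be > 0 or unbounded")
  }

  ids <- loc$id
  for (i in seq_len(nrow(rts))) {
    r <- rts[i, ]
    ent <- paste0(r$origin, "->", r$destination)
    if (!r$origin %in% ids)
      add(ent, "dangling_reference",
          paste0("route origin '", r$origin, "' is not a known location"))
    if (!r$destination %in% ids)
      add(ent, "dangling_reference",
          paste0("route destination '", r$destination,
                 "' is not a known location"))
    if (identical(r$origin, r$destination))
      add(ent, "route_endpoints", "origin and destination coincide")
    if (is.na(r$travel_h) || r$travel_h <= 0)
      add(ent, "travel_time", "travel time must be > 0")
    if (is.na(r$vehicle_m3) || r$vehicle_m3 <= 0)
      add(ent, "vehicle_volume", "vehicle volume must be > 0")
    if (is.na(r$leg_breakage_mean) || r$leg_breakage_mean < 0 ||
        r$leg_breakage_mean >= 1)
      add(ent, "leg_breakage", "leg breakage mean must lie in [0, 1)")
    if (is.na(r$review_period_d) || r$review_period_d <= 0)
      add(ent, "review_period", "review period must be > 0")
  }

  wh <- loc$id[loc$level == "wholesale_market"]
  for (i in seq_len(nrow(par))) {
    p <- par[i, ]
    ent <- paste0(p$a, "--", p$b)
    if (!p$a %in% wh || !p$b %in% wh)
      add(ent, "partner_membership",
          "partner edges must connect wholesale markets")
  }

  # Tier 3 markets: exactly one lateral trading partner.
  t3 <- loc$id[loc$level == "wholesale_market" & !is.na(loc$tier) &
                 loc$tier == 3L]
  deg <- table(c(par$a, par$b))
  for (m in t3) {
    d <- if (m %in% names(deg)) as.integer(deg[[m]]) else 0L
    if (d != 1L)
      add(m, "tier3_single_partner",
          paste0("tier 3 market has ", d, " wholesale partners (needs 1)"))
  }

  # Tier 1/2 subgraph connected.
  t12 <- loc$id[loc$level == "wholesale_market" & !is.na(loc$tier) &
                  loc$tier %in% 1:2]
  if (length(t12) > 1) {
    sub <- par[par$a %in% t12 & par$b %in% t12, , drop = FALSE]
    comp <- connected_component(t12[1], t12, sub)
    if (length(comp) < length(t12))
      add(paste(setdiff(t12, comp), collapse = ","), "tier12_connected",
          "tier 1/2 partner subgraph is not connected")
  }

  # Villages: exactly one outbound route to a wholesale market.
  vil <- loc$id[loc$level == "village_market"]
  for (v in vil) {
    out <- rts[rts$origin == v, , drop = FALSE]
    to_wh <- sum(out$destination %in% wh)
    if (to_wh != 1L)
      add(v, "village_single_wholesale",
          paste0("village market has ", to_wh,
                 " routes to wholesale markets (needs 1)"))
  }

  # Retailers: exactly one inbound route from a wholesale market.
  rt <- loc$id[loc$level %in% c("retailer", "surrogate_retail")]
  for (r in rt) {
    inb <- rts[rts$destination == r, , drop = FALSE]
    from_wh <- sum(inb$origin %in% wh)
    if (from_wh != 1L)
      add(r, "retailer_single_wholesale",
          paste0("retailer has ", from_wh,
                 " supplying wholesale markets (needs 1)"))
  }

  if (!length(bad)) {
    return(tibble::tibble(entity = character(), rule = character(),
                          detail = character()))
  }
  dplyr::bind_rows(bad)
}

# Breadth-first component of `start` within the undirected edge table.
connected_component <- function(start, nodes, edges) {
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nb <- c(edges$b[edges$a %in% frontier], edges$a[edges$b %in% frontier])
    nb <- setdiff(intersect(nb, nodes), seen)
    seen <- c(seen, nb)
    frontier <- nb
  }
  seen
}

#' Validate a crop parameter table
#'
#' @param crops Tibble with columns `name`, `lifespan_d` (ambient lifespan,
#'   days), `density_kg_m3` (bulk density), `demand_g_capita_d` (per-capita
#'   daily demand, grams), `production_ratio` (annual in-state production as
#'   a multiple of annual statewide consumer demand), monthly production
#'   weights `m1`..`m12`, and `cold_factor` (effective aging-rate multiplier
#'   in cold storage, in \[0, 1\]).
#' @return A tibble of violations (`entity`, `rule`, `detail`); zero rows if
#'   valid.
#' @export
validate_crops <- function(crops) {
  bad <- list()
  add <- function(entity, rule, detail) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(entity = entity, rule = rule,
                                               detail = detail)
  }
  need <- c("name", "lifespan_d", "density_kg_m3", "demand_g_capita_d",
            "production_ratio", paste0("m", 1:12), "cold_factor")
  miss <- setdiff(need, names(crops))
  if (length(miss)) {
    add("<table>", "missing_column", paste("missing columns:",
                                           paste(miss, collapse = ", ")))
    return(dplyr::bind_rows(bad))
  }
  for (i in seq_len(nrow(crops))) {
    cr <- crops[i, ]
    w <- as.numeric(cr[paste0("m", 1:12)])
    if (is.na(cr$lifespan_d) || cr$lifespan_d <= 0)
      add(cr$name, "lifespan", "ambient lifespan must be > 0 days")
    if (is.na(cr$density_kg_m3) || cr$density_kg_m3 <= 0)
      add(cr$name, "density", "bulk density must be > 0")
    if (is.na(cr$demand_g_capita_d) || cr$demand_g_capita_d < 0)
      add(cr$name, "demand", "per-capita demand must be >= 0")
    if (any(is.na(w)) || any(w < 0) || all(w == 0))
      add(cr$name, "season_weights",
          "monthly weights must be non-negative with at least one > 0")
    if (is.na(cr$cold_factor) || cr$cold_factor < 0 || cr$cold_factor > 1)
      add(cr$name, "cold_factor", "cold aging factor must lie in [0, 1]")
  }
  if (!length(bad)) {
    return(tibble::tibble(entity = character(), rule = character(),
                          detail = character()))
  }
  dplyr::bind_rows(bad)
}

#' Scenario configuration for a simulation run
#'
#' @param production_multiplier Factor applied to in-state village-market
#'   production (imports are held fixed unless `scale_imports = TRUE`).
#' @param burn_in Days of warm-up excluded from all outcome tallies while the
#'   empty chain fills to regular operation.
#' @param horizon Days of simulated, tallied time after the burn-in.
#' @param iterations Number of independent iterations of the scenario;
#'   iteration j uses seed `seed + j - 1`.
#' @param seed Integer seed for the first iteration.
#' @param stage_breakage_mean Mean broken fraction per storage stage (the
#'   per-transport-leg means live on the routes).
#' @param entry_noise_sigma Log-scale sigma of the unit-mean lognormal
#'   day-to-day noise on village production entries.
#' @param unit_mass_kg Discretisation unit for Poisson breakage counts.
#' @param scale_imports Should the production multiplier also scale imports?
#' @param departure_jitter_lambda Poisson parameter of the mean-zero
#'   integer-hour jitter applied to vehicle departures and consumer arrival
#'   times around their average hours.
#' @return A `scenario_config` object (named list).
#' @export
scenario_config <- function(production_multiplier = 1,
                            burn_in = 7,
                            horizon = 365,
                            iterations = 5,
                            seed = 1L,
                            stage_breakage_mean = 0.02,
                            entry_noise_sigma = 0.1,
                            unit_mass_kg = 1,
                            scale_imports = FALSE,
                            departure_jitter_lambda = 2) {
  stopifnot(production_multiplier > 0, burn_in >= 0, horizon >= 0,
            iterations >= 1, stage_breakage_mean >= 0,
            stage_breakage_mean < 1, unit_mass_kg > 0,
            entry_noise_sigma >= 0)
  structure(list(production_multiplier = production_multiplier,
                 burn_in = burn_in, horizon = horizon,
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 stage_breakage_mean = stage_breakage_mean,
                 entry_noise_sigma = entry_noise_sigma,
                 unit_mass_kg = unit_mass_kg,
                 scale_imports = isTRUE(scale_imports),
                 departure_jitter_lambda = departure_jitter_lambda),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> multiplier ", x$production_multiplier,
      ", burn-in ", x$burn_in, " d + horizon ", x$horizon, " d, ",
      x$iterations, " iteration(s), seed ", x$seed, "\n", sep = "")
  invisible(x)
}
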