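# Shared fixtures, built in code. Expensive simulation runs are memoised in
# a session cache so property tests can share them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Minimal one-village / one-wholesale / one-retailer chain.
toy_locations <- function(pop = 2000) {
  tibble::tibble(
    id = c("V001", "W001", "R0001"),
    level = c("village_market", "wholesale_market", "retailer"),
    tier = c(NA, 1L, NA),
    lat = c(20.0, 20.1, 20.15),
    lon = c(85.0, 85.1, 85.15),
    population = pop,
    direct_sale_fraction = c(0.05, 0.05, 0.9),
    storage_volume_m3 = Inf,
    arrival_hour = c(9, 11, 12))
}

toy_network <- function(leg_breakage_mean = 0.02, pop = 2000) {
  assign_nearest_partners(toy_locations(pop),
                          leg_breakage_mean = leg_breakage_mean)
}

# Ample, non-seasonal, long-lived variant of the default crops: production
# comfortably exceeds demand every month and nothing can expire within a
# short run.
ample_crops <- function(lifespan_d = 370, production_ratio = 3) {
  crops <- default_crops()
  crops$lifespan_d <- lifespan_d
  crops$production_ratio <- production_ratio
  crops[paste0("m", 1:12)] <- 1
  crops
}

small_params <- function(seed = 7) {
  generator_params(n_village = 10, n_tier1 = 1, n_tier2 = 1, n_tier3 = 3,
                   retailers_per_wholesale = 4, seed = seed)
}

small_network <- function(seed = 7, ...) {
  cached(paste0("small_net_", seed), generate_network(small_params(seed), ...))
}

# A short seeded run on the small network, shared across property tests.
small_run <- function(seed = 3, horizon = 20, multiplier = 1) {
  key <- sprintf("small_run_%d_%d_%s", seed, horizon, multiplier)
  cached(key, run_simulation(
    small_network(), default_crops(),
    scenario_config(production_multiplier = multiplier, horizon = horizon,
                    iterations = 1, seed = seed)))
}

# Hand-built veg_sim skeleton for metrics unit tests: `entered` kg of one
# crop, with losses/purchases/stock passed explicitly.
hand_result <- function(crop = "potato", entered = 100,
                        expired = c(wholesale_storage = 0),
                        broken = c(village_wholesale_transport = 0),
                        purchased = 0, exported = 0, end_stock = NULL) {
  stages <- c("village_storage", "village_wholesale_transport",
              "wholesale_storage", "wholesale_wholesale_transport",
              "wholesale_retail_transport", "retail_storage")
  exp_v <- setNames(numeric(6), stages)
  brk_v <- setNames(numeric(6), stages)
  exp_v[names(expired)] <- expired
  brk_v[names(broken)] <- broken
  if (is.null(end_stock)) {
    end_stock <- entered - purchased - exported - sum(exp_v) - sum(brk_v)
  }
  kind <- c("storage", "transport", "storage", "transport", "transport",
            "storage")
  losses <- dplyr::bind_rows(
    tibble::tibble(crop = crop, stage = stages, kind = kind,
                   mechanism = "expiration", mass_kg = unname(exp_v)),
    tibble::tibble(crop = crop, stage = stages, kind = kind,
                   mechanism = "breakage", mass_kg = unname(brk_v)))
  flows <- tibble::tibble(
    crop = crop, entered_production_kg = entered, entered_import_kg = 0,
    purchased_kg = purchased, exported_kg = exported,
    expired_kg = sum(exp_v), broken_kg = sum(brk_v),
    start_stock_kg = 0, start_intransit_kg = 0,
    end_stock_kg = end_stock, end_intransit_kg = 0)
  structure(list(
    tallies = tibble::tibble(crop = character(), location = character(),
                             level = character(), day = integer(),
                             arrivals = integer(), fulfilled = integer(),
                             purchased_kg = numeric()),
    losses = losses, flows = flows,
    chain_time = tibble::tibble(crop = crop, exited_kg = 0,
                                mean_days = NA_real_, max_days = NA_real_),
    chain_samples = tibble::tibble(crop = character(), days = numeric(),
                                   mass_kg = numeric()),
    config = scenario_config(horizon = 1, iterations = 1),
    meta = list(seed = 0L)), class = "veg_sim")
}
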