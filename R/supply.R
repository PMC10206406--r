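# Supply: entry of vegetables into the chain. Village-market production with
# monthly seasonality and day-to-day lognormal noise, plus a state-level
# import/export equilibrium: in any month where in-state production falls
# short of statewide consumer demand the deficit is imported at Tier 1
# wholesale markets, and any surplus is exported from Tier 1/2 markets, so
# that the chain as a whole always contains enough to meet average demand.

MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Calendar month of a simulation day
#'
#' Day 1 is January 1 of a 365-day year; days beyond 365 wrap around.
#'
#' @param day 1-based simulation day (numeric vector).
#' @return Integer month in 1..12.
#' @export
month_of_day <- function(day) {
  d <- ((as.integer(day) - 1L) %% 365L) + 1L
  findInterval(d, cumsum(c(1L, MONTH_DAYS[-12])))
}

#' Normalised seasonal production weight
#'
#' Weights are normalised by their mean so that the yearly average of the
#' returned weight is 1 and annual production equals the annual base rate.
#'
#' @param crop One row of a crop table (or a list with `m1`..`m12`).
#' @param month Month(s) in 1..12.
#' @return Normalised weight(s).
#' @export
seasonal_weight <- function(crop, month) {
  stopifnot(all(month %in% 1:12))
  w <- as.numeric(crop[paste0("m", 1:12)])
  if (all(w == 0)) stop("all-zero season weights for crop ", crop$name)
  (w / mean(w))[month]
}

#' Build the supply plan: production rates, imports and exports
#'
#' Statewide daily consumer demand per crop is the population-weighted sum
#' of per-capita demand over all selling locations. Annual in-state
#' production is `production_ratio` times annual demand, distributed across
#' village markets proportionally to their catchment populations and across
#' months by the crop's seasonal weights. For each (crop, month), any
#' production deficit relative to demand becomes an import rate (entering at
#' Tier 1 wholesale markets, split equally) and any surplus becomes an
#' export rate (an external-sink demand served from Tier 1/2 markets after
#' local consumers), so supply = demand holds each month.
#'
#' @param network A validated [veg_network()] containing at least one
#'   village market, and at least one Tier 1 wholesale market whenever any
#'   month runs a deficit.
#' @param crops Crop table (see [validate_crops()]).
#' @return A `veg_supply_plan`: list of tibbles `entries` (crop, location,
#'   month, rate_kg_d), `imports` and `exports` (crop, month, rate_kg_d),
#'   and `demand` (crop, statewide_kg_d).
#' @export
build_supply_plan <- function(network, crops) {
  loc <- network$locations
  sell <- loc$population * loc$direct_sale_fraction
  vil <- loc[loc$level == "village_market", , drop = FALSE]
  if (!nrow(vil)) stop("network has no village markets")
  vshare <- vil$population
  vshare <- if (sum(vshare) > 0) vshare / sum(vshare) else
    rep(1 / nrow(vil), nrow(vil))

  t1 <- loc$id[loc$level == "wholesale_market" & !is.na(loc$tier) &
                 loc$tier == 1L]

  entries <- list()
  imports <- list()
  exports <- list()
  demand <- list()
  for (i in seq_len(nrow(crops))) {
    cr <- crops[i, ]
    d_day <- sum(sell) * cr$demand_g_capita_d / 1000 # kg/day statewide
    demand[[i]] <- tibble::tibble(crop = cr$name, statewide_kg_d = d_day)
    w <- seasonal_weight(cr, 1:12)
    prod_day <- cr$production_ratio * d_day * w # kg/day statewide, by month
    deficit <- pmax(0, d_day - prod_day)
    surplus <- pmax(0, prod_day - d_day)
    if (any(deficit > 0) && !length(t1))
      stop("imports needed for crop '", cr$name,
           "' but the network has no Tier 1 wholesale market")
    entries[[i]] <- tibble::tibble(
      crop = cr$name,
      location = rep(vil$id, times = 12),
      month = rep(1:12, each = nrow(vil)),
      rate_kg_d = as.vector(outer(vshare, prod_day)))
    imports[[i]] <- tibble::tibble(crop = cr$name, month = 1:12,
                                   rate_kg_d = deficit)
    exports[[i]] <- tibble::tibble(crop = cr$name, month = 1:12,
                                   rate_kg_d = surplus)
  }
  structure(list(entries = dplyr::bind_rows(entries),
                 imports = dplyr::bind_rows(imports),
                 exports = dplyr::bind_rows(exports),
                 demand = dplyr::bind_rows(demand)),
            class = "veg_supply_plan")
}

#' @export
print.veg_supply_plan <- function(x, ...) {
  cat("<veg_supply_plan> ", dplyr::n_distinct(x$entries$crop), " crops x ",
      dplyr::n_distinct(x$entries$location), " village markets; statewide demand ",
      round(sum(x$demand$statewide_kg_d)), " kg/d\n", sep = "")
  invisible(x)
}

#' Draw one day's village-market production entries
#'
#' Each village market's entering mass is `multiplier * plan rate *
#' day-to-day noise`, where the noise is unit-mean lognormal with log-scale
#' sigma `sigma` (seasonality is already folded into the monthly plan
#' rates). The multiplier scales in-state production only; import entries
#' are handled separately by the engine.
#'
#' @param plan A [build_supply_plan()].
#' @param day 1-based simulation day.
#' @param multiplier Production multiplier (> 0).
#' @param sigma Lognormal day-to-day noise sigma (0 disables noise).
#' @param stream An [rng_stream()] for the noise draws.
#' @return Tibble (crop, location, mass_kg) in plan row order.
#' @export
daily_entries <- function(plan, day, multiplier, sigma = 0.1,
                          stream = NULL) {
  stopifnot(multiplier > 0)
  m <- month_of_day(day)
  e <- plan$entries[plan$entries$month == m, , drop = FALSE]
  noise <- if (sigma > 0) {
    if (is.null(stream)) stop("a stream is required when sigma > 0")
    rs_lnorm_unit(stream, nrow(e), sigma)
  } else rep(1, nrow(e))
  tibble::tibble(crop = e$crop, location = e$location,
                 mass_kg = multiplier * e$rate_kg_d * noise)
}
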