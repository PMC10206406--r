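# Trade: route construction by geographic proximity, order computation,
# lateral wholesale-to-wholesale trade under bounded information, and
# perishability-prioritised vehicle loading.

#' Great-circle distance in kilometres
#'
#' Haversine formula with Earth radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees (vectorised).
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

default_policy <- function(initiator, review = 1, safety = 1) {
  list(quantity_mode = "variable", frequency_mode = "fixed",
       initiator = initiator, persistence = "persistent",
       review_period_d = review, safety_stock_d = safety,
       fixed_quantity_kg = NA_real_)
}

#' Build routes and the wholesale partner graph by geographic proximity
#'
#' Each village market ships to its nearest wholesale market
#' (supplier-delivers), each retailer fetches from its nearest wholesale
#' market (recipient-fetches, order-up-to policy), each Tier 3 wholesale
#' market gets exactly one lateral trading partner (its nearest Tier 1/2
#' market), and the Tier 1/2 markets are fully interconnected among
#' themselves. Distance ties are broken by lowest location id. Travel times
#' are distance / `speed_kmh` with a floor of `min_travel_h`; lateral
#' routes use a fixed `lateral_travel_h`.
#'
#' @param locations A locations tibble (see [veg_network()]).
#' @param speed_kmh Road speed used to convert distance to travel time.
#' @param min_travel_h Floor on travel time, hours.
#' @param lateral_travel_h Travel time between wholesale trading partners.
#' @param village_vehicle_m3,retail_vehicle_m3,lateral_vehicle_m3 Vehicle
#'   volumes by route type (a "vehicle" abstracts the day's total haulage
#'   on the link).
#' @param leg_breakage_mean Mean broken fraction per transport leg.
#' @param village_depart_hour,retail_depart_hour,lateral_depart_hour Mean
#'   departure hours-of-day.
#' @return A [veg_network()] combining `locations` with the derived routes
#'   and partner edges.
#' @export
assign_nearest_partners <- function(locations,
                                    speed_kmh = 40,
                                    min_travel_h = 0.2,
                                    lateral_travel_h = 5,
                                    village_vehicle_m3 = 200,
                                    retail_vehicle_m3 = 20,
                                    lateral_vehicle_m3 = 80,
                                    leg_breakage_mean = 0.02,
                                    village_depart_hour = 6,
                                    retail_depart_hour = 7,
                                    lateral_depart_hour = 16) {
  loc <- tibble::as_tibble(locations)
  wh <- loc[loc$level == "wholesale_market", , drop = FALSE]
  if (!nrow(wh)) stop("no wholesale markets present")

  nearest <- function(lat, lon, cand) {
    d <- haversine_km(lat, lon, cand$lat, cand$lon)
    # tie-break: lowest id
    cand$id[order(d, cand$id)][1]
  }

  routes <- list()
  add_route <- function(origin, destination, vehicle, travel, dep, pol) {
    routes[[length(routes) + 1L]] <<- tibble::tibble(
      origin = origin, destination = destination, vehicle_m3 = vehicle,
      travel_h = travel, depart_hour = dep,
      quantity_mode = pol$quantity_mode, frequency_mode = pol$frequency_mode,
      initiator = pol$initiator, persistence = pol$persistence,
      review_period_d = pol$review_period_d,
      safety_stock_d = pol$safety_stock_d,
      fixed_quantity_kg = pol$fixed_quantity_kg,
      leg_breakage_mean = leg_breakage_mean)
  }

  travel_to <- function(lat, lon, id) {
    w <- wh[wh$id == id, ]
    max(min_travel_h, haversine_km(lat, lon, w$lat, w$lon) / speed_kmh)
  }

  vil <- loc[loc$level == "village_market", , drop = FALSE]
  for (i in seq_len(nrow(vil))) {
    v <- vil[i, ]
    to <- nearest(v$lat, v$lon, wh)
    add_route(v$id, to, village_vehicle_m3, travel_to(v$lat, v$lon, to),
              village_depart_hour, default_policy("supplier_delivers"))
  }

  rt <- loc[loc$level %in% c("retailer", "surrogate_retail"), , drop = FALSE]
  for (i in seq_len(nrow(rt))) {
    r <- rt[i, ]
    from <- nearest(r$lat, r$lon, wh)
    add_route(from, r$id, retail_vehicle_m3, travel_to(r$lat, r$lon, from),
              retail_depart_hour, default_policy("recipient_fetches"))
  }

  # Partner graph: Tier 1/2 complete among themselves; each Tier 3 attaches
  # to its nearest Tier 1/2 market.
  t12 <- wh[wh$tier %in% 1:2, , drop = FALSE]
  t3 <- wh[wh$tier == 3L, , drop = FALSE]
  partners <- list()
  if (nrow(t12) > 1) {
    cmb <- utils::combn(sort(t12$id), 2)
    partners[[1]] <- tibble::tibble(a = cmb[1, ], b = cmb[2, ])
  }
  if (nrow(t3)) {
    if (!nrow(t12)) stop("tier 3 markets present but no tier 1/2 markets")
    up <- vapply(seq_len(nrow(t3)),
                 function(i) nearest(t3$lat[i], t3$lon[i], t12), "")
    partners[[length(partners) + 1L]] <- tibble::tibble(a = t3$id, b = up)
  }
  partners <- if (length(partners)) dplyr::bind_rows(partners) else
    tibble::tibble(a = character(), b = character())

  # One lateral transport route per partner edge (used in both directions).
  for (i in seq_len(nrow(partners))) {
    add_route(partners$a[i], partners$b[i], lateral_vehicle_m3,
              lateral_travel_h, lateral_depart_hour,
              default_policy("supplier_delivers"))
  }

  veg_network(loc, dplyr::bind_rows(routes), partners)
}

#' Compute a replenishment order quantity
#'
#' Variable-quantity mode is an order-up-to (base-stock) rule: order up to
#' `(review_period + safety_stock)` days of demand, netting on-hand and
#' in-transit stock. Fixed-quantity mode orders the configured constant
#' whenever projected coverage falls below the same target. Vectorised over
#' the rows of `estimate`.
#'
#' @param policy List or one-row tibble with `quantity_mode`,
#'   `review_period_d`, `safety_stock_d`, `fixed_quantity_kg`.
#' @param estimate Tibble with columns `daily_demand_kg`, `on_hand_kg`,
#'   `in_transit_kg`.
#' @return Order quantities in kg (one per estimate row).
#' @export
compute_order <- function(policy, estimate) {
  stopifnot(all(estimate$daily_demand_kg >= 0),
            all(estimate$on_hand_kg >= 0),
            all(estimate$in_transit_kg >= 0))
  target <- (policy$review_period_d + policy$safety_stock_d) *
    estimate$daily_demand_kg
  gap <- target - estimate$on_hand_kg - estimate$in_transit_kg
  if (identical(policy$quantity_mode, "fixed")) {
    ifelse(gap > 0, policy$fixed_quantity_kg, 0)
  } else {
    pmax(0, gap)
  }
}

#' Plan lateral transfers between wholesale trading partners
#'
#' For each crop, a market whose projected stock (on hand + inbound
#' in-transit) covers less than one day of its downstream demand requests
#' the shortfall from the direct trading partner with the largest projected
#' surplus. Information is restricted to direct partners — no new edges are
#' created and no market sees beyond its partners — and a sender never
#' ships below one day of its own downstream demand. Transfers are planned
#' deficit-market by deficit-market in id order, drawing down sender
#' surpluses as they are committed.
#'
#' @param partners Tibble of undirected partner edges (`a`, `b`).
#' @param estimates Tibble with columns `market`, `crop`,
#'   `daily_demand_kg` (the market's estimated downstream daily demand,
#'   including any Tier 3 partners it alone supplies), `on_hand_kg`,
#'   `in_transit_kg`, and optionally `reserve_kg` (the stock a sender will
#'   not ship below; defaults to `daily_demand_kg`).
#' @return Tibble of transfer orders (`from`, `to`, `crop`, `quantity_kg`).
#' @export
lateral_transfers <- function(partners, estimates) {
  out <- list()
  adj <- split(c(partners$b, partners$a), c(partners$a, partners$b))
  for (cr in sort(unique(estimates$crop))) {
    e <- estimates[estimates$crop == cr, , drop = FALSE]
    e <- e[order(e$market), , drop = FALSE]
    on_hand <- setNames(e$on_hand_kg, e$market)
    proj <- e$on_hand_kg + e$in_transit_kg - e$daily_demand_kg
    names(proj) <- e$market
    demand <- setNames(e$daily_demand_kg, e$market)
    # shippable surplus: what exceeds one day of the sender's reserve on hand
    reserve <- if ("reserve_kg" %in% names(e)) e$reserve_kg else
      e$daily_demand_kg
    avail <- setNames(pmax(0, on_hand - reserve), e$market)
    for (mkt in e$market[proj < 0]) {
      need <- -proj[[mkt]]
      prt <- intersect(adj[[mkt]], names(avail))
      if (!length(prt)) next
      best <- prt[order(-avail[prt], prt)][1]
      q <- min(need, avail[[best]])
      if (q <= 0) next
      avail[[best]] <- avail[[best]] - q
      out[[length(out) + 1L]] <- tibble::tibble(
        from = best, to = mkt, crop = cr, quantity_kg = q)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(from = character(), to = character(),
                          crop = character(), quantity_kg = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Pack a vehicle with perishability priority
#'
#' Lot volume is `mass / bulk_density`. Lots are sorted most-perishable
#' first (crop lifespan ascending, then effective age descending) and packed
#' greedily until the vehicle volume is exhausted; the boundary lot may be
#' split. Less perishable items are left behind when space runs out.
#'
#' @param lots A [lot_tibble()].
#' @param vehicle_m3 Vehicle volume (> 0).
#' @param crops Crop table (`name`, `lifespan_d`, `density_kg_m3`).
#' @return List of lot tibbles `loaded` and `left_behind`; their masses sum
#'   to the input mass exactly.
#' @export
load_vehicle <- function(lots, vehicle_m3, crops) {
  stopifnot(vehicle_m3 > 0)
  if (!nrow(lots)) return(list(loaded = lots, left_behind = lots))
  lifespan <- setNames(crops$lifespan_d, crops$name)
  density <- setNames(crops$density_kg_m3, crops$name)
  ord <- order(lifespan[lots$crop], -lots$effective_age_d)
  lots <- lots[ord, , drop = FALSE]
  vol <- lots$mass_kg / density[lots$crop]
  cs <- cumsum(vol)
  if (cs[length(cs)] <= vehicle_m3 + 1e-12) {
    return(list(loaded = lots, left_behind = lots[0, , drop = FALSE]))
  }
  k <- findInterval(vehicle_m3 + 1e-12, cs) + 1L
  loaded <- lots[seq_len(k - 1L), , drop = FALSE]
  left <- lots[seq(k, nrow(lots)), , drop = FALSE]
  room <- vehicle_m3 - if (k > 1L) cs[k - 1L] else 0
  if (room > 1e-12) {
    split_mass <- room * density[lots$crop[k]]
    piece <- lots[k, , drop = FALSE]
    piece$mass_kg <- split_mass
    loaded <- dplyr::bind_rows(loaded, piece)
    left$mass_kg[1] <- left$mass_kg[1] - split_mass
  }
  list(loaded = loaded, left_behind = left)
}
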