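# The discrete event run loop. State lives in one environment: per-location
# inventories are (crop, mass, age, entry) matrices aged lazily to the time
# of the event that touches them; outcome tallies are arrays indexed
# (crop, location, day) and (crop, stage); randomness comes from four
# labelled streams (supply, breakage, arrivals, departures) so that the
# production multiplier cannot perturb the supply noise sequence.

STREAM_LABELS <- c("supply", "breakage", "arrivals", "departures")

#' Run one simulation iteration
#'
#' Processes events in time order from t = 0 through `burn_in + horizon`
#' days. Outcome tallies (arrivals, purchases, losses, exits) accumulate
#' only after the burn-in; the stock and in-transit mass present at the
#' burn-in boundary are snapshotted so that mass balance holds exactly over
#' the tallied window. The run is a deterministic function of
#' `(network, crops, config, seed)`.
#'
#' @param network A [veg_network()]; must pass [validate_network()].
#' @param crops A crop table; must pass [validate_crops()].
#' @param config A [scenario_config()].
#' @param seed Seed for this iteration (defaults to `config$seed`).
#' @param village_reserve_days Days of local direct demand a village market
#'   holds back from outbound shipments for its own consumers.
#' @param wholesale_reserve_days Days of local direct demand a wholesale
#'   market holds back from retail fetches and exports.
#' @return A `veg_sim` object: list of tibbles `tallies` (crop, location,
#'   level, day, arrivals, fulfilled, purchased_kg), `losses` (crop, stage,
#'   kind, mechanism, mass_kg), `flows` (per-crop mass accounts),
#'   `chain_time` (per-crop time-through-chain aggregates) and
#'   `chain_samples`, plus `config` and `meta`.
#' @export
run_simulation <- function(network, crops, config, seed = NULL,
                           village_reserve_days = 1.5,
                           wholesale_reserve_days = 1.5) {
  t0 <- proc.time()[["elapsed"]]
  viol <- validate_network(network)
  if (nrow(viol)) {
    stop("invalid network (", nrow(viol), " violation(s)); first: ",
         viol$entity[1], ": ", viol$detail[1])
  }
  cv <- validate_crops(crops)
  if (nrow(cv)) {
    stop("invalid crop table; first: ", cv$entity[1], ": ", cv$detail[1])
  }
  if (is.null(seed)) seed <- config$seed
  S <- compile_state(network, crops, config, seed,
                     village_reserve_days, wholesale_reserve_days)

  q <- new_event_queue()
  schedule_event(q, 0, "daily_cycle", list(day = 1L))
  if (S$t_burn > 0) schedule_event(q, S$t_burn, "burn_in_snapshot")
  schedule_event(q, S$t_end, "end_of_run")
  if (S$t_burn == 0) snapshot_burn_in(S, 0)

  repeat {
    ev <- next_event(q)
    if (is.null(ev)) break
    if (ev$kind == "end_of_run") {
      finish_run(S, ev$time)
      break
    }
    t <- ev$time
    p <- ev$payload
    switch(ev$kind,
           daily_cycle = h_daily_cycle(S, q, t, p$day),
           burn_in_snapshot = snapshot_burn_in(S, t),
           production_entry = h_production(S, t, p$day),
           vehicle_departure = h_departure(S, q, t, p),
           vehicle_arrival = h_arrival(S, t, p),
           consumer_arrival = h_consumer(S, t, p$loc),
           daily_review = h_review(S, q, t, p$day),
           export_draw = h_export(S, t, p$day),
           expiration_sweep = h_sweep(S, t),
           stop("unhandled event kind: ", ev$kind))
  }
  assemble_result(S, seed, proc.time()[["elapsed"]] - t0)
}

# ---------------------------------------------------------------------------
# state compilation

compile_state <- function(network, crops, config, seed,
                          village_reserve_days, wholesale_reserve_days) {
  S <- new.env(parent = emptyenv())
  loc <- network$locations
  S$config <- config
  S$crops <- crops
  S$network_counts <- table(loc$level)
  S$K <- nrow(crops)
  S$crop_names <- crops$name
  S$L <- crops$lifespan_d
  S$dens <- crops$density_kg_m3
  S$percap_kg <- crops$demand_g_capita_d / 1000

  S$nloc <- nrow(loc)
  S$id <- loc$id
  S$level <- loc$level
  S$tier <- loc$tier
  S$pop <- loc$population
  S$dsf <- loc$direct_sale_fraction
  S$arr_hour <- loc$arrival_hour
  idx <- setNames(seq_len(S$nloc), S$id)

  S$vil <- which(loc$level == "village_market")
  S$wh <- which(loc$level == "wholesale_market")
  S$rt <- which(loc$level %in% c("retailer", "surrogate_retail"))
  S$sellers <- which(S$pop * S$dsf > 0 & loc$level != "external")
  S$t1 <- which(loc$level == "wholesale_market" & !is.na(loc$tier) &
                  loc$tier == 1L)
  S$t12 <- which(loc$level == "wholesale_market" & !is.na(loc$tier) &
                   loc$tier %in% 1:2)

  # daily direct (local) consumer demand, kg, per (crop, location)
  S$local_demand <- outer(S$percap_kg, S$pop * S$dsf)
  S$village_reserve <- village_reserve_days * S$local_demand
  S$wh_direct_reserve <- wholesale_reserve_days * S$local_demand

  # storage stage index a lot enters at each location
  stg <- match(storage_stage_of_level(loc$level), STAGES)
  S$store_stage <- stg

  rts <- network$routes
  wh_ids <- S$id[S$wh]
  is_v <- rts$origin %in% S$id[S$vil] & rts$destination %in% wh_ids
  is_r <- rts$origin %in% wh_ids & rts$destination %in% S$id[S$rt]
  vr <- rts[is_v, , drop = FALSE]
  rr <- rts[is_r, , drop = FALSE]
  lr <- rts[!is_v & !is_r, , drop = FALSE]
  S$vroutes <- list(from = idx[vr$origin], to = idx[vr$destination],
                    travel = vr$travel_h, vol = vr$vehicle_m3,
                    dep_hour = vr$depart_hour, brk = vr$leg_breakage_mean)
  S$rroutes <- list(from = idx[rr$origin], to = idx[rr$destination],
                    travel = rr$travel_h, vol = rr$vehicle_m3,
                    dep_hour = rr$depart_hour, brk = rr$leg_breakage_mean,
                    review = rr$review_period_d, safety = rr$safety_stock_d,
                    qmode = rr$quantity_mode, fixedq = rr$fixed_quantity_kg)

  # lateral route lookup by unordered market pair
  lat_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  S$lat <- list()
  for (i in seq_len(nrow(lr))) {
    S$lat[[lat_key(lr$origin[i], lr$destination[i])]] <-
      list(travel = lr$travel_h[i], vol = lr$vehicle_m3[i],
           brk = lr$leg_breakage_mean[i], dep_hour = lr$depart_hour[i])
  }
  S$lat_key <- lat_key
  S$partners <- network$partners

  # retail demand attached to each wholesale market
  S$retail_attached <- matrix(0, S$K, S$nloc)
  for (j in seq_along(S$rroutes$from)) {
    w <- S$rroutes$from[j]
    S$retail_attached[, w] <- S$retail_attached[, w] +
      S$local_demand[, S$rroutes$to[j]]
  }
  S$wh_demand_static <- S$local_demand + S$retail_attached

  # daily information sharing: a Tier 3 market's downstream demand is
  # communicated to the Tier 1/2 partner that alone supplies it
  S$child_demand <- matrix(0, S$K, S$nloc)
  t3_ids <- S$id[S$wh][!is.na(S$tier[S$wh]) & S$tier[S$wh] == 3L]
  for (cid in t3_ids) {
    pid <- c(network$partners$b[network$partners$a == cid],
             network$partners$a[network$partners$b == cid])
    if (length(pid) == 1L) {
      pi <- idx[pid]
      S$child_demand[, pi] <- S$child_demand[, pi] +
        S$wh_demand_static[, idx[cid]]
    }
  }

  # supply plan compiled to matrices
  plan <- build_supply_plan(network, crops)
  S$plan <- plan
  nv <- length(S$vil)
  S$entry_rate <- array(0, c(S$K, nv, 12))
  vil_pos <- setNames(seq_len(nv), S$id[S$vil])
  k_of <- setNames(seq_len(S$K), S$crop_names)
  e <- plan$entries
  S$entry_rate[cbind(k_of[e$crop], vil_pos[e$location], e$month)] <- e$rate_kg_d
  S$import_rate <- matrix(0, S$K, 12)
  S$import_rate[cbind(k_of[plan$imports$crop], plan$imports$month)] <-
    plan$imports$rate_kg_d
  S$export_rate <- matrix(0, S$K, 12)
  S$export_rate[cbind(k_of[plan$exports$crop], plan$exports$month)] <-
    plan$exports$rate_kg_d
  S$k_of <- k_of

  # clock bounds
  S$t_burn <- config$burn_in * 24
  S$t_end <- (config$burn_in + config$horizon) * 24
  S$D <- config$horizon
  S$mult <- config$production_multiplier
  S$sigma <- config$entry_noise_sigma
  S$stage_rate <- config$stage_breakage_mean
  S$unit <- config$unit_mass_kg
  S$jit_lambda <- config$departure_jitter_lambda
  S$scale_imports <- config$scale_imports

  S$streams <- make_rng_streams(seed, STREAM_LABELS)

  # dynamic state
  S$inv <- rep(list(empty_lots()), S$nloc)
  S$last_t <- numeric(S$nloc)
  S$intransit <- matrix(0, S$K, S$nloc)

  # tallies
  d <- max(1L, S$D)
  S$arr <- array(0L, c(S$K, S$nloc, d))
  S$ful <- array(0L, c(S$K, S$nloc, d))
  S$pur <- array(0, c(S$K, S$nloc, d))
  S$expired <- matrix(0, S$K, length(STAGES))
  S$broken <- matrix(0, S$K, length(STAGES))
  S$entered_prod <- numeric(S$K)
  S$entered_imp <- numeric(S$K)
  S$exported <- numeric(S$K)
  S$start_stock <- numeric(S$K)
  S$start_intransit <- numeric(S$K)
  S$end_stock <- numeric(S$K)
  S$end_intransit <- numeric(S$K)
  S$tic_w <- numeric(S$K)   # sum(mass * days-in-chain)
  S$tic_m <- numeric(S$K)   # sum(mass) over exits
  S$tic_max <- numeric(S$K)
  S$samples <- lapply(seq_len(S$K), function(k) list())
  S$samples_n <- integer(S$K)
  S$samples_cap <- 3000L
  S
}

empty_lots <- function() {
  matrix(numeric(0), ncol = 4,
         dimnames = list(NULL, c("crop", "mass", "age", "entry")))
}

# ---------------------------------------------------------------------------
# inventory primitives (matrix mirrors of the exported lot-tibble functions)

inv_age_to <- function(S, i, t) {
  el <- t - S$last_t[i]
  if (el > 0) {
    M <- S$inv[[i]]
    if (nrow(M)) {
      M[, 3L] <- M[, 3L] + el / 24
      S$inv[[i]] <- M
    }
    S$last_t[i] <- t
  }
  invisible(NULL)
}

inv_expire <- function(S, i, t, stage, tally = TRUE) {
  M <- S$inv[[i]]
  if (!nrow(M)) return(invisible(NULL))
  gone <- M[, 3L] >= S$L[M[, 1L]]
  if (any(gone)) {
    G <- M[gone, , drop = FALSE]
    if (tally && t >= S$t_burn) {
      for (k in unique(G[, 1L])) {
        rows <- G[, 1L] == k
        S$expired[k, stage] <- S$expired[k, stage] + sum(G[rows, 2L])
        tally_exit(S, k, G[rows, 2L], G[rows, 4L], t)
      }
    }
    S$inv[[i]] <- M[!gone, , drop = FALSE]
  }
  invisible(NULL)
}

inv_totals <- function(S, i) {
  M <- S$inv[[i]]
  tot <- numeric(S$K)
  if (nrow(M)) {
    agg <- rowsum(M[, 2L], M[, 1L])
    tot[as.integer(rownames(agg))] <- agg[, 1L]
  }
  tot
}

# FEFO removal of `amount` kg of crop k; returns the removed rows.
inv_take <- function(S, i, k, amount) {
  M <- S$inv[[i]]
  rows <- which(M[, 1L] == k)
  if (!length(rows) || amount <= 0) return(empty_lots())
  ord <- rows[order(-M[rows, 3L], M[rows, 4L])]
  m <- M[ord, 2L]
  cs <- cumsum(m)
  total <- cs[length(cs)]
  if (amount >= total - 1e-12) {
    taken <- M[ord, , drop = FALSE]
    S$inv[[i]] <- M[-ord, , drop = FALSE]
    return(taken)
  }
  kfull <- findInterval(amount - 1e-12, cs)
  part_amt <- amount - if (kfull > 0) cs[kfull] else 0
  taken_rows <- if (kfull > 0) ord[seq_len(kfull)] else integer(0)
  taken <- M[taken_rows, , drop = FALSE]
  drop_rows <- taken_rows
  if (part_amt > 1e-12) {
    pr <- ord[kfull + 1L]
    piece <- M[pr, , drop = FALSE]
    piece[1L, 2L] <- part_amt
    taken <- rbind(taken, piece)
    left <- M[pr, 2L] - part_amt
    if (left <= 1e-12) {
      drop_rows <- c(drop_rows, pr)
    } else {
      M[pr, 2L] <- left
    }
  }
  if (length(drop_rows)) M <- M[-drop_rows, , drop = FALSE]
  S$inv[[i]] <- M
  taken
}

inv_add <- function(S, i, lots) {
  if (nrow(lots)) S$inv[[i]] <- rbind(S$inv[[i]], lots)
  invisible(NULL)
}

tally_exit <- function(S, k, masses, entries, t) {
  if (t < S$t_burn) return(invisible(NULL))
  dt <- (t - entries) / 24
  S$tic_w[k] <- S$tic_w[k] + sum(masses * dt)
  S$tic_m[k] <- S$tic_m[k] + sum(masses)
  mx <- max(dt)
  if (mx > S$tic_max[k]) S$tic_max[k] <- mx
  if (S$samples_n[k] < S$samples_cap) {
    S$samples[[k]][[length(S$samples[[k]]) + 1L]] <- cbind(dt, masses)
    S$samples_n[k] <- S$samples_n[k] + length(dt)
  }
  invisible(NULL)
}

# Proportional breakage removal across lots of each crop present in M.
# Returns list(M = surviving lots, broken = per-crop broken kg vector).
break_lots <- function(S, M, rate, t, stage) {
  broken <- numeric(S$K)
  if (!nrow(M) || rate <= 0) return(list(M = M, broken = broken))
  ks <- sort(unique(M[, 1L]))
  mass_k <- vapply(ks, function(k) sum(M[M[, 1L] == k, 2L]), 0)
  draw <- pmin(rs_pois(S$streams$breakage, length(ks),
                       rate * mass_k / S$unit) * S$unit, mass_k)
  for (j in seq_along(ks)) {
    if (draw[j] <= 0) next
    k <- ks[j]
    f <- draw[j] / mass_k[j]
    rows <- M[, 1L] == k
    lost <- M[rows, 2L] * f
    if (t >= S$t_burn) {
      S$broken[k, stage] <- S$broken[k, stage] + draw[j]
      tally_exit(S, k, lost, M[rows, 4L], t)
    }
    M[rows, 2L] <- M[rows, 2L] - lost
    broken[k] <- draw[j]
  }
  keep <- M[, 2L] > 1e-12
  list(M = M[keep, , drop = FALSE], broken = broken)
}

jitter_hours <- function(S, n = 1) {
  rs_pois(S$streams$departures, n, S$jit_lambda) - S$jit_lambda
}

# ---------------------------------------------------------------------------
# event handlers

h_daily_cycle <- function(S, q, t, day) {
  if (t >= S$t_end) return(invisible(NULL))
  schedule_event(q, t + 5, "production_entry", list(day = day))
  nv <- length(S$vroutes$from)
  if (nv) {
    jit <- jitter_hours(S, nv)
    dep <- pmin(pmax(S$vroutes$dep_hour + jit, 4), 9)
    for (j in seq_len(nv)) {
      schedule_event(q, t + dep[j], "vehicle_departure",
                     list(type = "village", route = j))
    }
  }
  ns <- length(S$sellers)
  if (ns) {
    # consumers arrive during market hours, after morning deliveries and
    # before the 15:00 demand-information review
    jit <- rs_pois(S$streams$arrivals, ns, S$jit_lambda) - S$jit_lambda
    hr <- pmin(pmax(S$arr_hour[S$sellers] + jit, 6), 14.5)
    for (j in seq_len(ns)) {
      schedule_event(q, t + hr[j], "consumer_arrival",
                     list(loc = S$sellers[j]))
    }
  }
  schedule_event(q, t + 15, "daily_review", list(day = day))
  schedule_event(q, t + 20, "export_draw", list(day = day))
  schedule_event(q, t + 23.5, "expiration_sweep")
  if (t + 24 < S$t_end) {
    schedule_event(q, t + 24, "daily_cycle", list(day = day + 1L))
  }
  invisible(NULL)
}

h_production <- function(S, t, day) {
  m <- month_of_day(day)
  nv <- length(S$vil)
  rate <- S$entry_rate[, , m, drop = FALSE]  # K x nv
  dim(rate) <- c(S$K, nv)
  noise <- matrix(rs_lnorm_unit(S$streams$supply, S$K * nv, S$sigma),
                  S$K, nv, byrow = FALSE)
  mass <- S$mult * rate * noise
  tallying <- t >= S$t_burn
  for (j in seq_len(nv)) {
    mk <- mass[, j]
    ks <- which(mk > 1e-9)
    if (!length(ks)) next
    i <- S$vil[j]
    inv_age_to(S, i, t)
    if (tallying) S$entered_prod[ks] <- S$entered_prod[ks] + mk[ks]
    lots <- cbind(crop = ks, mass = mk[ks], age = 0, entry = t)
    res <- break_lots(S, lots, S$stage_rate, t, 1L) # village storage stage
    inv_add(S, i, res$M)
  }
  # imports enter at Tier 1 wholesale markets, split equally
  imp <- S$import_rate[, m]
  if (S$scale_imports) imp <- imp * S$mult
  if (any(imp > 0) && length(S$t1)) {
    per <- imp / length(S$t1)
    for (i in S$t1) {
      ks <- which(per > 1e-9)
      inv_age_to(S, i, t)
      if (tallying) S$entered_imp[ks] <- S$entered_imp[ks] + per[ks]
      lots <- cbind(crop = ks, mass = per[ks], age = 0, entry = t)
      res <- break_lots(S, lots, S$stage_rate, t, 3L) # wholesale storage stage
      inv_add(S, i, res$M)
    }
  }
  invisible(NULL)
}

h_departure <- function(S, q, t, p) {
  if (p$type == "village") {
    r <- lapply(S$vroutes, `[`, p$route)
    i <- r$from
    inv_age_to(S, i, t)
    inv_expire(S, i, t, 1L)
    tot <- inv_totals(S, i)
    want <- pmax(0, tot - S$village_reserve[, i])
    dispatch_shipment(S, q, t, i, r$to, want, r$vol, r$travel, r$brk,
                      leg_stage = 2L)
  } else if (p$type == "retail") {
    r <- lapply(S$rroutes, `[`, p$route)
    i <- r$from
    inv_age_to(S, i, t)
    inv_expire(S, i, t, 3L)
    tot <- inv_totals(S, i)
    avail <- pmax(0, tot - S$wh_direct_reserve[, i])
    want <- pmin(p$qty, avail)
    dispatch_shipment(S, q, t, i, r$to, want, r$vol, r$travel, r$brk,
                      leg_stage = 5L)
  } else { # lateral
    i <- p$from
    inv_age_to(S, i, t)
    inv_expire(S, i, t, 3L)
    tot <- inv_totals(S, i)
    m <- month_of_day(floor(t / 24) + 1)
    reserve <- S$wh_demand_static[, i] + export_share(S, i, m)
    avail <- pmax(0, tot - reserve)
    want <- pmin(p$qty, avail)
    lt <- S$lat[[S$lat_key(S$id[i], S$id[p$to])]]
    dispatch_shipment(S, q, t, i, p$to, want, lt$vol, lt$travel, lt$brk,
                      leg_stage = 4L)
  }
  invisible(NULL)
}

# Take `want` (per-crop kg) FEFO from location i, pack the vehicle with
# perishability priority, return the overflow to inventory, and put the
# loaded lots in transit.
dispatch_shipment <- function(S, q, t, i, to, want, vol, travel, brk,
                              leg_stage) {
  ks <- which(want > 1e-9)
  if (!length(ks)) return(invisible(NULL))
  cand <- do.call(rbind, lapply(ks, function(k) inv_take(S, i, k, want[k])))
  if (!nrow(cand)) return(invisible(NULL))
  packed <- pack_vehicle(S, cand, vol)
  inv_add(S, i, packed$left)
  M <- packed$loaded
  if (!nrow(M)) return(invisible(NULL))
  dep_mass <- numeric(S$K)
  agg <- rowsum(M[, 2L], M[, 1L])
  dep_mass[as.integer(rownames(agg))] <- agg[, 1L]
  S$intransit[, to] <- S$intransit[, to] + dep_mass
  schedule_event(q, t + travel, "vehicle_arrival",
                 list(lots = M, to = to, dep_time = t, dep_mass = dep_mass,
                      brk = brk, leg_stage = leg_stage))
  invisible(NULL)
}

# Matrix mirror of load_vehicle(): most perishable first, boundary lot split.
pack_vehicle <- function(S, M, vol_m3) {
  ord <- order(S$L[M[, 1L]], -M[, 3L])
  M <- M[ord, , drop = FALSE]
  v <- M[, 2L] / S$dens[M[, 1L]]
  cs <- cumsum(v)
  if (cs[length(cs)] <= vol_m3 + 1e-12) {
    return(list(loaded = M, left = empty_lots()))
  }
  kfull <- findInterval(vol_m3 + 1e-12, cs)
  loaded <- M[seq_len(kfull), , drop = FALSE]
  left <- M[seq(kfull + 1L, nrow(M)), , drop = FALSE]
  room <- vol_m3 - if (kfull > 0) cs[kfull] else 0
  if (room > 1e-12) {
    split_mass <- room * S$dens[left[1L, 1L]]
    piece <- left[1L, , drop = FALSE]
    piece[1L, 2L] <- split_mass
    loaded <- rbind(loaded, piece)
    left[1L, 2L] <- left[1L, 2L] - split_mass
    if (left[1L, 2L] <= 1e-12) left <- left[-1L, , drop = FALSE]
  }
  list(loaded = loaded, left = left)
}

h_arrival <- function(S, t, p) {
  M <- p$lots
  M[, 3L] <- M[, 3L] + (t - p$dep_time) / 24
  # expiration in transit
  gone <- M[, 3L] >= S$L[M[, 1L]]
  if (any(gone)) {
    G <- M[gone, , drop = FALSE]
    if (t >= S$t_burn) {
      for (k in unique(G[, 1L])) {
        rows <- G[, 1L] == k
        S$expired[k, p$leg_stage] <- S$expired[k, p$leg_stage] +
          sum(G[rows, 2L])
        tally_exit(S, k, G[rows, 2L], G[rows, 4L], t)
      }
    }
    M <- M[!gone, , drop = FALSE]
  }
  res <- break_lots(S, M, p$brk, t, p$leg_stage)     # leg breakage
  res <- break_lots(S, res$M, S$stage_rate, t,        # entry into storage
                    S$store_stage[p$to])
  S$intransit[, p$to] <- S$intransit[, p$to] - p$dep_mass
  inv_age_to(S, p$to, t)
  inv_add(S, p$to, res$M)
  invisible(NULL)
}

h_consumer <- function(S, t, i) {
  inv_age_to(S, i, t)
  inv_expire(S, i, t, S$store_stage[i])
  n <- rs_pois(S$streams$arrivals, 1L, S$pop[i] * S$dsf[i])
  if (n == 0L) {
    if (t >= S$t_burn) tally_day(S, t, i, integer(0), NULL, NULL, NULL)
    return(invisible(NULL))
  }
  tot <- inv_totals(S, i)
  served <- numeric(S$K)
  fulfilled <- integer(S$K)
  for (k in seq_len(S$K)) {
    req <- S$percap_kg[k]
    if (req <= 0) { fulfilled[k] <- n; next }
    take <- min(tot[k], n * req)
    fulfilled[k] <- min(n, as.integer(floor(take / req + 1e-9)))
    if (take > 0) {
      taken <- inv_take(S, i, k, take)
      served[k] <- take
      if (t >= S$t_burn) tally_exit(S, k, taken[, 2L], taken[, 4L], t)
    }
  }
  if (t >= S$t_burn) {
    d <- min(S$D, floor((t - S$t_burn) / 24) + 1L)
    S$arr[, i, d] <- S$arr[, i, d] + n
    S$ful[, i, d] <- S$ful[, i, d] + fulfilled
    S$pur[, i, d] <- S$pur[, i, d] + served
  }
  invisible(NULL)
}

tally_day <- function(S, t, i, ...) invisible(NULL)

h_review <- function(S, q, t, day) {
  m <- month_of_day(day)
  for (i in S$wh) {
    inv_age_to(S, i, t)
    inv_expire(S, i, t, 3L)
  }
  # retailer replenishment: order-up-to, executed as next-morning fetches
  nr <- length(S$rroutes$from)
  for (j in seq_len(nr)) {
    rt <- S$rroutes$to[j]
    d_r <- S$local_demand[, rt]
    oh <- inv_totals(S, rt)
    it <- S$intransit[, rt]
    target <- (S$rroutes$review[j] + S$rroutes$safety[j]) * d_r
    qty <- if (identical(S$rroutes$qmode[j], "fixed")) {
      ifelse(target - oh - it > 0, S$rroutes$fixedq[j], 0)
    } else {
      pmax(0, target - oh - it)
    }
    if (sum(qty) > 1e-9) {
      dep <- floor(t / 24) * 24 + 24 +
        min(max(S$rroutes$dep_hour[j] + jitter_hours(S), 5), 9)
      schedule_event(q, dep, "vehicle_departure",
                     list(type = "retail", route = j, qty = qty))
    }
  }
  # lateral wholesale trade, restricted to direct partners
  if (nrow(S$partners) && length(S$wh)) {
    est <- list()
    for (i in S$wh) {
      ex <- export_share(S, i, m)
      # pass-through stock for tier 3 children carries two review periods
      # of their demand (request latency + onward transfer latency), the
      # usual base-stock allowance for the extra hop
      est[[length(est) + 1L]] <- tibble::tibble(
        market = S$id[i], crop = S$crop_names,
        daily_demand_kg = S$wh_demand_static[, i] +
          2 * S$child_demand[, i] + ex,
        reserve_kg = S$wh_demand_static[, i] + ex,
        on_hand_kg = inv_totals(S, i),
        in_transit_kg = S$intransit[, i])
    }
    tr <- lateral_transfers(S$partners, dplyr::bind_rows(est))
    if (nrow(tr)) {
      pairs <- paste(tr$from, tr$to, sep = "\r")
      for (pk in unique(pairs)) {
        sub <- tr[pairs == pk, , drop = FALSE]
        qty <- numeric(S$K)
        qty[S$k_of[sub$crop]] <- sub$quantity_kg
        from_i <- match(sub$from[1], S$id)
        to_i <- match(sub$to[1], S$id)
        lt <- S$lat[[S$lat_key(sub$from[1], sub$to[1])]]
        dep <- floor(t / 24) * 24 +
          min(max(lt$dep_hour + jitter_hours(S), 15), 20)
        schedule_event(q, dep, "vehicle_departure",
                       list(type = "lateral", from = from_i, to = to_i,
                            qty = qty))
      }
    }
  }
  invisible(NULL)
}

export_share <- function(S, i, m) {
  if (!length(S$t12) || !(i %in% S$t12)) return(numeric(S$K))
  S$export_rate[, m] / length(S$t12)
}

h_export <- function(S, t, day) {
  m <- month_of_day(day)
  rate <- S$export_rate[, m]
  if (all(rate <= 0) || !length(S$t12)) return(invisible(NULL))
  for (k in which(rate > 0)) {
    need <- rate[k]
    # draw from the markets with the most shippable surplus first
    # exports are served last: hold back local direct sales plus the full
    # order-up-to claim (two review periods) of dependent retailers. The
    # day's lateral transfers to tier 3 partners have already departed by
    # the evening export draw, so no pass-through stock is reserved here.
    avail <- vapply(S$t12, function(i) {
      inv_age_to(S, i, t)
      max(0, inv_totals(S, i)[k] - S$wh_direct_reserve[k, i] -
            2 * S$retail_attached[k, i])
    }, 0)
    for (i in S$t12[order(-avail)]) {
      if (need <= 1e-9) break
      a <- avail[match(i, S$t12)]
      take <- min(need, a)
      if (take <= 1e-9) next
      taken <- inv_take(S, i, k, take)
      got <- sum(taken[, 2L])
      need <- need - got
      if (t >= S$t_burn) {
        S$exported[k] <- S$exported[k] + got
        tally_exit(S, k, taken[, 2L], taken[, 4L], t)
      }
    }
  }
  invisible(NULL)
}

h_sweep <- function(S, t) {
  for (i in seq_len(S$nloc)) {
    if (!nrow(S$inv[[i]])) { S$last_t[i] <- t; next }
    inv_age_to(S, i, t)
    inv_expire(S, i, t, S$store_stage[i])
  }
  invisible(NULL)
}

snapshot_burn_in <- function(S, t) {
  for (i in seq_len(S$nloc)) {
    inv_age_to(S, i, t)
    inv_expire(S, i, t, S$store_stage[i], tally = FALSE)
    S$start_stock <- S$start_stock + inv_totals(S, i)
  }
  S$start_intransit <- rowSums(S$intransit)
  invisible(NULL)
}

finish_run <- function(S, t) {
  for (i in seq_len(S$nloc)) {
    inv_age_to(S, i, t)
    inv_expire(S, i, t, S$store_stage[i])
    S$end_stock <- S$end_stock + inv_totals(S, i)
  }
  S$end_intransit <- rowSums(S$intransit)
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# result assembly

assemble_result <- function(S, seed, wall_s) {
  sellers <- S$sellers
  D <- max(1L, S$D)
  tallies <- tibble::tibble(
    crop = rep(rep(S$crop_names, times = length(sellers)), times = D),
    location = rep(rep(S$id[sellers], each = S$K), times = D),
    level = rep(rep(S$level[sellers], each = S$K), times = D),
    day = rep(seq_len(D), each = S$K * length(sellers)),
    arrivals = as.integer(S$arr[, sellers, , drop = FALSE]),
    fulfilled = as.integer(S$ful[, sellers, , drop = FALSE]),
    purchased_kg = as.numeric(S$pur[, sellers, , drop = FALSE]))
  if (S$D == 0L) tallies <- tallies[0, , drop = FALSE]

  losses <- tidyr::expand_grid(crop = S$crop_names, stage = STAGES) |>
    dplyr::mutate(kind = unname(STAGE_KIND[.data$stage]))
  losses$expiration <- as.numeric(t(S$expired))
  losses$breakage <- as.numeric(t(S$broken))
  losses <- tidyr::pivot_longer(losses, c("expiration", "breakage"),
                                names_to = "mechanism",
                                values_to = "mass_kg")

  flows <- tibble::tibble(
    crop = S$crop_names,
    entered_production_kg = S$entered_prod,
    entered_import_kg = S$entered_imp,
    purchased_kg = vapply(seq_len(S$K),
                          function(k) sum(S$pur[k, , ]), 0),
    exported_kg = S$exported,
    expired_kg = rowSums(S$expired),
    broken_kg = rowSums(S$broken),
    start_stock_kg = S$start_stock,
    start_intransit_kg = S$start_intransit,
    end_stock_kg = S$end_stock,
    end_intransit_kg = S$end_intransit)

  chain_time <- tibble::tibble(
    crop = S$crop_names,
    exited_kg = S$tic_m,
    mean_days = ifelse(S$tic_m > 0, S$tic_w / S$tic_m, NA_real_),
    max_days = ifelse(S$tic_m > 0, S$tic_max, NA_real_))

  chain_samples <- dplyr::bind_rows(lapply(seq_len(S$K), function(k) {
    if (!length(S$samples[[k]])) {
      return(tibble::tibble(crop = character(), days = numeric(),
                            mass_kg = numeric()))
    }
    m <- do.call(rbind, S$samples[[k]])
    tibble::tibble(crop = S$crop_names[k], days = m[, 1L], mass_kg = m[, 2L])
  }))

  structure(list(tallies = tallies, losses = losses, flows = flows,
                 chain_time = chain_time, chain_samples = chain_samples,
                 config = S$config,
                 meta = list(seed = seed, wall_s = wall_s,
                             locations = S$network_counts,
                             crops = S$crops)),
            class = "veg_sim")
}

#' @export
print.veg_sim <- function(x, ...) {
  cat("<veg_sim> seed ", x$meta$seed, ", multiplier ",
      x$config$production_multiplier, ", ", x$config$horizon,
      " tallied day(s)\n", sep = "")
  ent <- sum(x$flows$entered_production_kg + x$flows$entered_import_kg)
  cat("  entered ", round(ent), " kg; purchased ",
      round(sum(x$flows$purchased_kg)), " kg; lost ",
      round(sum(x$flows$expired_kg + x$flows$broken_kg)), " kg\n", sep = "")
  invisible(x)
}

#' Run a scenario: several iterations of one configuration
#'
#' Iteration j runs with seed `config$seed + j - 1`; reported metrics are
#' arithmetic means across iterations.
#'
#' @inheritParams run_simulation
#' @return A `veg_scenario`: list with `results` (list of `veg_sim`) and
#'   `config`.
#' @export
run_scenario <- function(network, crops, config, ...) {
  results <- lapply(seq_len(config$iterations) - 1L, function(j) {
    run_simulation(network, crops, config, seed = config$seed + j, ...)
  })
  structure(list(results = results, config = config), class = "veg_scenario")
}

#' @export
print.veg_scenario <- function(x, ...) {
  cat("<veg_scenario> multiplier ", x$config$production_multiplier, ", ",
      length(x$results), " iteration(s)\n", sep = "")
  invisible(x)
}

#' Run the production-multiplier experiment
#'
#' @inheritParams run_simulation
#' @param multipliers Production multipliers to simulate.
#' @return List of `veg_scenario`, one per multiplier.
#' @export
run_suite <- function(network, crops, config,
                      multipliers = c(1, 1.25, 1.5, 2, 3, 5), ...) {
  lapply(multipliers, function(m) {
    cfg <- config
    cfg$production_multiplier <- m
    run_scenario(network, crops, cfg, ...)
  })
}
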