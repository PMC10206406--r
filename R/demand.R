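# Consumer demand: Poisson arrivals per selling location, per-capita
# purchase requests, FEFO dispatch, and fulfillment accounting. An arrival
# requests the crop's full per-capita daily demand; fulfillment is binary
# per crop per arrival (partial quantities are sold but counted
# unfulfilled), and demand is constant across the year.

#' Draw a day's consumer arrival count at a location
#'
#' Arrivals are Poisson with mean `population * direct_sale_fraction`: each
#' member of the direct-sale share of the catchment makes on average one
#' visit per day.
#'
#' @param location One row of a locations table (needs `population` and
#'   `direct_sale_fraction`).
#' @param stream An [rng_stream()].
#' @param n Number of days to draw.
#' @return Integer vector of arrival counts.
#' @export
consumer_arrival_count <- function(location, stream, n = 1) {
  mu <- location$population * location$direct_sale_fraction
  stopifnot(mu >= 0)
  if (mu == 0) return(rep(0L, n))
  rs_pois(stream, n, mu)
}

# Take `amount` kg of `crop` from a lot tibble in FEFO order (largest
# effective age first; ties by earlier entry). Returns the reduced lots, the
# mass taken, and the mass-weighted sum of entry times of the taken mass
# (for time-in-chain accounting).
fefo_take <- function(lots, crop, amount) {
  rows <- which(lots$crop == crop)
  if (!length(rows) || amount <= 0) {
    return(list(lots = lots, taken_kg = 0, entry_wsum = 0))
  }
  ord <- rows[order(-lots$effective_age_d[rows], lots$entry_time_h[rows])]
  m <- lots$mass_kg[ord]
  cs <- cumsum(m)
  k <- findInterval(amount - 1e-12, cs) + 1L
  if (k > length(ord)) { # everything taken
    taken <- cs[length(cs)]
    wsum <- sum(m * lots$entry_time_h[ord])
    lots <- lots[-ord, , drop = FALSE]
    return(list(lots = lots, taken_kg = taken, entry_wsum = wsum))
  }
  take_full <- if (k > 1L) ord[seq_len(k - 1L)] else integer(0)
  part <- ord[k]
  part_amt <- amount - if (k > 1L) cs[k - 1L] else 0
  wsum <- sum(lots$mass_kg[take_full] * lots$entry_time_h[take_full]) +
    part_amt * lots$entry_time_h[part]
  lots$mass_kg[part] <- lots$mass_kg[part] - part_amt
  drop <- c(take_full, if (lots$mass_kg[part] <= 1e-12) part)
  if (length(drop)) lots <- lots[-drop, , drop = FALSE]
  list(lots = lots, taken_kg = amount, entry_wsum = wsum)
}

#' Serve one consumer arrival from an inventory (FEFO dispatch)
#'
#' Inventory is drawn oldest-effective-age-first. The fulfilled flag for a
#' crop is `TRUE` iff the full requested quantity was served; a partial
#' quantity is still sold (and removed from inventory) but counts as
#' unfulfilled.
#'
#' @param lots A [lot_tibble()] inventory.
#' @param requested_g Named numeric: grams requested per crop.
#' @return List with `lots` (reduced inventory), `served_kg` (named) and
#'   `fulfilled` (named logical).
#' @export
serve_arrival <- function(lots, requested_g) {
  stopifnot(all(requested_g >= 0))
  served <- setNames(numeric(length(requested_g)), names(requested_g))
  fulfilled <- setNames(logical(length(requested_g)), names(requested_g))
  for (crop in names(requested_g)) {
    req_kg <- requested_g[[crop]] / 1000
    if (req_kg == 0) { fulfilled[[crop]] <- TRUE; next }
    avail <- sum(lots$mass_kg[lots$crop == crop])
    take <- min(avail, req_kg)
    res <- fefo_take(lots, crop, take)
    lots <- res$lots
    served[[crop]] <- res$taken_kg
    fulfilled[[crop]] <- res$taken_kg >= req_kg - 1e-12
  }
  list(lots = lots, served_kg = served, fulfilled = fulfilled)
}

#' Demand fulfillment fraction over a filtered scope
#'
#' The proportion of consumer-arrival instances at which the requested crop
#' was fully available, over the tallies selected by the filters.
#'
#' @param result A [run_simulation()] result (or any tibble with columns
#'   `crop`, `level`, `location`, `day`, `arrivals`, `fulfilled`).
#' @param crop,level,location Optional filters (character vectors).
#' @param days Optional day range `c(first, last)`.
#' @return Fraction in \[0, 1\], or `NA_real_` (with a warning) when the
#'   scope contains no arrivals — undefined, which is distinct from 0.
#' @export
fulfillment_fraction <- function(result, crop = NULL, level = NULL,
                                 location = NULL, days = NULL) {
  tal <- if (inherits(result, "veg_sim")) result$tallies else result
  if (!is.null(crop)) tal <- tal[tal$crop %in% crop, , drop = FALSE]
  if (!is.null(level)) tal <- tal[tal$level %in% level, , drop = FALSE]
  if (!is.null(location)) tal <- tal[tal$location %in% location, , drop = FALSE]
  if (!is.null(days)) tal <- tal[tal$day >= days[1] & tal$day <= days[2], ,
                                 drop = FALSE]
  n <- sum(tal$arrivals)
  if (n == 0) {
    warning("no consumer arrivals in the filtered scope; fulfillment undefined")
    return(NA_real_)
  }
  sum(tal$fulfilled) / n
}
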