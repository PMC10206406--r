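# Aging, expiration and breakage: the model's two loss mechanisms.
# A lot is a row (crop, mass_kg, effective_age_d, entry_time_h). Lots degrade
# at a linear rate until their effective age reaches the crop's ambient
# lifespan, at which point they expire (closed boundary: age >= lifespan).
# Breakage is a Poisson count of broken unit-mass pieces per storage stage
# or transport leg.

#' Lot tibble constructor
#'
#' @param crop Crop names.
#' @param mass_kg Lot masses (kg).
#' @param effective_age_d Effective ages (days; advances slower in cold
#'   storage).
#' @param entry_time_h Simulation time at which each lot entered the chain.
#' @return A tibble of lots.
#' @export
lot_tibble <- function(crop = character(), mass_kg = numeric(),
                       effective_age_d = numeric(),
                       entry_time_h = numeric()) {
  tibble::tibble(crop = as.character(crop), mass_kg = mass_kg,
                 effective_age_d = effective_age_d,
                 entry_time_h = entry_time_h)
}

#' Effective aging rate by storage kind
#'
#' Ambient storage and transit age produce at the nominal rate of one day
#' per elapsed day; cold storage slows aging by the crop's cold factor.
#'
#' @param storage_kind One of `"ambient"`, `"cold"`, `"transit"`.
#' @param cold_factor The crop's cold aging factor in \[0, 1\] (only used
#'   when `storage_kind == "cold"`).
#' @return Days of effective age accrued per elapsed day.
#' @export
effective_aging_rate <- function(storage_kind, cold_factor = 1) {
  switch(storage_kind,
         ambient = 1,
         transit = 1,
         cold = cold_factor,
         stop("unknown storage kind: ", storage_kind))
}

#' Age lots by an elapsed interval
#'
#' @param lots A [lot_tibble()].
#' @param elapsed_h Elapsed wall time in hours (>= 0).
#' @param storage_kind Storage kind the lots sat in; see
#'   [effective_aging_rate()].
#' @param crops Crop table (needed for per-crop cold factors when
#'   `storage_kind == "cold"`).
#' @return The lots with `effective_age_d` advanced; masses unchanged.
#' @export
age_lots <- function(lots, elapsed_h, storage_kind = "ambient",
                     crops = NULL) {
  if (elapsed_h < 0) stop("elapsed time must be >= 0")
  if (!nrow(lots) || elapsed_h == 0) return(lots)
  if (storage_kind == "cold") {
    if (is.null(crops)) stop("crops table required for cold storage aging")
    cf <- unname(setNames(crops$cold_factor, crops$name)[lots$crop])
    rate <- vapply(cf, function(x) effective_aging_rate("cold", x), 0)
  } else {
    rate <- effective_aging_rate(storage_kind)
  }
  lots$effective_age_d <- lots$effective_age_d + (elapsed_h / 24) * rate
  lots
}

#' Remove expired lots from an inventory
#'
#' A lot is expired iff its effective age has reached its crop's ambient
#' lifespan (closed boundary: `age >= lifespan` expires). Mass is conserved
#' between the two outputs.
#'
#' @param lots A [lot_tibble()].
#' @param crops Crop table with `name` and `lifespan_d`.
#' @return List with `surviving` (a lot tibble) and `expired_kg` (named
#'   numeric, one entry per crop in `crops`).
#' @export
remove_expired <- function(lots, crops) {
  expired_kg <- setNames(numeric(nrow(crops)), crops$name)
  if (!nrow(lots)) return(list(surviving = lots, expired_kg = expired_kg))
  lifespan <- setNames(crops$lifespan_d, crops$name)[lots$crop]
  gone <- lots$effective_age_d >= lifespan
  if (any(gone)) {
    tal <- tapply(lots$mass_kg[gone], lots$crop[gone], sum)
    expired_kg[names(tal)] <- unname(tal)
  }
  list(surviving = lots[!gone, , drop = FALSE], expired_kg = expired_kg)
}

#' Draw Poisson breakage on a mass
#'
#' Breakage is discretised in `unit_mass_kg` pieces: the number of broken
#' units is Poisson with mean `mean_rate * mass / unit_mass_kg`, capped so
#' broken mass never exceeds the mass at risk.
#'
#' @param mass_kg Mass at risk (kg, >= 0).
#' @param mean_rate Mean broken fraction per stage/leg, in \[0, 1).
#' @param unit_mass_kg Discretisation unit (kg, > 0).
#' @param stream An [rng_stream()] to draw from.
#' @return Broken mass in kg (a multiple of `unit_mass_kg`, capped at
#'   `mass_kg`).
#' @export
draw_breakage <- function(mass_kg, mean_rate, unit_mass_kg, stream) {
  if (any(mass_kg < 0)) stop("mass must be >= 0")
  stopifnot(mean_rate >= 0, mean_rate < 1, unit_mass_kg > 0)
  if (mean_rate == 0) return(rep(0, length(mass_kg)))
  units_at_risk <- mass_kg / unit_mass_kg
  broken_units <- rs_pois(stream, length(mass_kg), mean_rate * units_at_risk)
  pmin(broken_units * unit_mass_kg, mass_kg)
}
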