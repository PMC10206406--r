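# File formats: plain comma-separated tables with header rows for networks,
# crops and results; YAML for scenario configuration; a JSON run manifest;
# optional GeoJSON export of locations for mapping.

LOCATION_COLUMNS <- c("id", "level", "tier", "lat", "lon", "population",
                      "direct_sale_fraction", "storage_volume_m3",
                      "arrival_hour")
ROUTE_COLUMNS <- c("origin", "destination", "vehicle_m3", "travel_h",
                   "depart_hour", "quantity_mode", "frequency_mode",
                   "initiator", "persistence", "review_period_d",
                   "safety_stock_d", "fixed_quantity_kg",
                   "leg_breakage_mean")
CROP_COLUMNS <- c("name", "lifespan_d", "density_kg_m3", "demand_g_capita_d",
                  "production_ratio", paste0("m", 1:12), "cold_factor")

read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("missing ", what, " file: ", path)
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, " file ", basename(path), " is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning("ignoring unknown column(s) in ", basename(path), ": ",
            paste(extra, collapse = ", "))
    df <- df[required]
  }
  df
}

#' Read a network from a directory of delimited tables
#'
#' Expects `locations.csv`, `routes.csv` and `partners.csv` (the partner
#' file may be absent when there is no lateral trade). Unknown columns are
#' dropped with a warning; missing required columns and dangling route
#' references are errors naming the offending column or id.
#'
#' @param dir Directory containing the tables.
#' @return A [veg_network()].
#' @export
read_network_tables <- function(dir) {
  loc <- read_table_checked(file.path(dir, "locations.csv"),
                            LOCATION_COLUMNS, "locations")
  rts <- read_table_checked(file.path(dir, "routes.csv"),
                            ROUTE_COLUMNS, "routes")
  ppath <- file.path(dir, "partners.csv")
  par <- if (file.exists(ppath)) {
    read_table_checked(ppath, c("a", "b"), "partners")
  } else {
    tibble::tibble(a = character(), b = character())
  }
  bad <- setdiff(c(rts$origin, rts$destination), loc$id)
  if (length(bad)) {
    stop("routes reference unknown location id(s): ",
         paste(unique(bad), collapse = ", "))
  }
  if (any(is.na(loc$lat)) || any(is.na(loc$lon))) {
    stop("malformed coordinates for location(s): ",
         paste(loc$id[is.na(loc$lat) | is.na(loc$lon)], collapse = ", "))
  }
  veg_network(loc, rts, par)
}

#' Write a network to a directory of delimited tables
#'
#' @param network A [veg_network()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_network_tables <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  loc <- network$locations[LOCATION_COLUMNS]
  # Inf does not round-trip through read.csv; blank means unbounded
  loc$storage_volume_m3[is.infinite(loc$storage_volume_m3)] <- NA
  write.csv(loc, file.path(dir, "locations.csv"), row.names = FALSE,
            na = "")
  write.csv(network$routes[ROUTE_COLUMNS], file.path(dir, "routes.csv"),
            row.names = FALSE, na = "")
  write.csv(network$partners, file.path(dir, "partners.csv"),
            row.names = FALSE, na = "")
  invisible(dir)
}

#' Read or write a crop parameter table
#'
#' @param path CSV path.
#' @return `read_crop_table`: a crop tibble; invalid tables are an error
#'   naming the first violation.
#' @export
read_crop_table <- function(path) {
  crops <- read_table_checked(path, CROP_COLUMNS, "crops")
  v <- validate_crops(crops)
  if (nrow(v)) {
    stop("invalid crop table: ", v$entity[1], ": ", v$detail[1])
  }
  crops
}

#' @rdname read_crop_table
#' @param crops Crop tibble.
#' @export
write_crop_table <- function(crops, path) {
  write.csv(crops[CROP_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Write simulation results as delimited tables plus a manifest
#'
#' Emits per-iteration `tallies_<j>.csv`, `losses_<j>.csv` and
#' `flows_<j>.csv`, a `chain_time.csv`, an iteration-averaged
#' `summary.csv` (the [scenario_summary()] table), and a `manifest.json`
#' echoing the configuration, seeds, package version and wall time.
#'
#' @param scenario A `veg_scenario` (or single `veg_sim`).
#' @param dir Output directory.
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(scenario, dir) {
  if (inherits(scenario, "veg_sim")) {
    scenario <- structure(list(results = list(scenario),
                               config = scenario$config),
                          class = "veg_scenario")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (j in seq_along(scenario$results)) {
    res <- scenario$results[[j]]
    f1 <- file.path(dir, sprintf("tallies_%d.csv", j))
    f2 <- file.path(dir, sprintf("losses_%d.csv", j))
    f3 <- file.path(dir, sprintf("flows_%d.csv", j))
    write.csv(res$tallies, f1, row.names = FALSE)
    write.csv(loss_breakdown(res), f2, row.names = FALSE)
    write.csv(res$flows, f3, row.names = FALSE)
    files <- c(files, f1, f2, f3)
  }
  ct <- dplyr::bind_rows(lapply(scenario$results, time_in_chain_stats),
                         .id = "iteration")
  fct <- file.path(dir, "chain_time.csv")
  write.csv(ct, fct, row.names = FALSE)
  fsum <- file.path(dir, "summary.csv")
  write.csv(scenario_summary(scenario), fsum, row.names = FALSE)
  fman <- file.path(dir, "manifest.json")
  manifest <- list(
    config = unclass(scenario$config),
    seeds = vapply(scenario$results, function(r) r$meta$seed, 0L),
    wall_s = sum(vapply(scenario$results, function(r) r$meta$wall_s, 0)),
    package_version = as.character(packageVersion("vegchain")),
    files = basename(c(files, fct, fsum)))
  jsonlite::write_json(manifest, fman, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(files, chain_time = fct, summary = fsum, manifest = fman))
}

#' Read a scenario configuration from a YAML file
#'
#' Keys mirror the arguments of [scenario_config()]; absent keys take the
#' defaults.
#'
#' @param path YAML file.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "))
  }
  do.call(scenario_config, raw[intersect(names(raw), known)])
}

#' Export locations as GeoJSON for mapping
#'
#' @param locations A locations tibble.
#' @param path Output path.
#' @export
write_locations_geojson <- function(locations, path) {
  features <- lapply(seq_len(nrow(locations)), function(i) {
    l <- locations[i, ]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(l$lon, l$lat)),
         properties = list(id = l$id, level = l$level,
                           tier = if (is.na(l$tier)) NULL else l$tier,
                           population = l$population))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
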