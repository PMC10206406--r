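# Outcome metrics: loss breakdown by mechanism and stage, the mass-balance
# conservation audit, time-through-chain statistics, and scenario summary
# tables for the production-multiplier experiments. All loss fractions are
# mass-based; exports count as successful exits, not losses.

#' Postharvest loss breakdown for a run
#'
#' Loss as a fraction of the mass that entered the supply chain (production
#' plus imports), split by mechanism (expiration vs breakage) and by the
#' six supply chain stages, each classified storage vs transport. The
#' mechanism and stage splits each sum exactly to the total.
#'
#' @param result A `veg_sim` from [run_simulation()].
#' @param crop Optional crop filter.
#' @return Tibble (crop, stage, kind, mechanism, mass_kg, frac_of_entered).
#' @export
loss_breakdown <- function(result, crop = NULL) {
  entered <- result$flows$entered_production_kg +
    result$flows$entered_import_kg
  names(entered) <- result$flows$crop
  out <- result$losses
  if (!is.null(crop)) out <- out[out$crop %in% crop, , drop = FALSE]
  if (any(entered[unique(out$crop)] <= 0)) {
    stop("zero entered mass for crop(s): ",
         paste(names(entered)[entered <= 0], collapse = ", "))
  }
  out$frac_of_entered <- out$mass_kg / entered[out$crop]
  out
}

#' Per-crop total loss summary
#'
#' @inheritParams loss_breakdown
#' @return Tibble (crop, entered_kg, total_loss, expiration_loss,
#'   breakage_loss, storage_loss, transport_loss), all losses as fractions
#'   of entered mass.
#' @export
loss_summary <- function(result) {
  lb <- loss_breakdown(result)
  lb |>
    dplyr::group_by(.data$crop) |>
    dplyr::summarise(
      total_loss = sum(.data$frac_of_entered),
      expiration_loss = sum(.data$frac_of_entered[
        .data$mechanism == "expiration"]),
      breakage_loss = sum(.data$frac_of_entered[
        .data$mechanism == "breakage"]),
      storage_loss = sum(.data$frac_of_entered[.data$kind == "storage"]),
      transport_loss = sum(.data$frac_of_entered[.data$kind == "transport"]),
      .groups = "drop") |>
    dplyr::left_join(
      dplyr::transmute(result$flows, crop = .data$crop,
                       entered_kg = .data$entered_production_kg +
                         .data$entered_import_kg),
      by = "crop") |>
    dplyr::relocate("entered_kg", .after = "crop")
}

#' Mass-balance conservation audit
#'
#' Everything that entered the tallied window (mass on hand and in transit
#' at the burn-in boundary, plus production and import entries) must exit
#' it (purchases, exports, expiration, breakage) or remain (ending stock,
#' in transit at the end). The residual should be zero to floating-point
#' accuracy; the contract used throughout the test suite is
#' `|residual| <= 1e-6 * entered`.
#'
#' @param result A `veg_sim`.
#' @return Tibble (crop, entered_kg, residual_kg, relative).
#' @export
mass_balance_residual <- function(result) {
  f <- result$flows
  inflow <- f$start_stock_kg + f$start_intransit_kg +
    f$entered_production_kg + f$entered_import_kg
  outflow <- f$purchased_kg + f$exported_kg + f$expired_kg + f$broken_kg +
    f$end_stock_kg + f$end_intransit_kg
  tibble::tibble(crop = f$crop,
                 entered_kg = f$entered_production_kg + f$entered_import_kg,
                 residual_kg = inflow - outflow,
                 relative = ifelse(inflow > 0,
                                   abs(inflow - outflow) / inflow, 0))
}

#' Time-through-chain statistics
#'
#' Mass-weighted mean and maximum days between a unit of mass entering the
#' chain and exiting it (consumption, export, or loss), with quantiles from
#' the per-run exit sample.
#'
#' @param result A `veg_sim`.
#' @return Tibble (crop, exited_kg, mean_days, max_days, q25, q50, q75, q90).
#' @export
time_in_chain_stats <- function(result) {
  if (all(result$chain_time$exited_kg == 0)) stop("no exits recorded")
  qs <- result$chain_samples |>
    dplyr::group_by(.data$crop) |>
    dplyr::summarise(
      q25 = weighted_quantile(.data$days, .data$mass_kg, 0.25),
      q50 = weighted_quantile(.data$days, .data$mass_kg, 0.50),
      q75 = weighted_quantile(.data$days, .data$mass_kg, 0.75),
      q90 = weighted_quantile(.data$days, .data$mass_kg, 0.90),
      .groups = "drop")
  dplyr::left_join(result$chain_time, qs, by = "crop")
}

weighted_quantile <- function(x, w, p) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= p)[1]]
}

#' Summarise scenarios for the multiplier experiment
#'
#' One row per (multiplier, crop), averaged over scenario iterations:
#' retail-level demand fulfillment, total loss and its storage/transport
#' split, and entered mass. The table is the input to
#' [plot_scenario_summary()] (availability and losses against the
#' production multiplier).
#'
#' @param scenarios A `veg_scenario` or list of them (e.g. [run_suite()]).
#' @return Tibble (multiplier, crop, retail_fulfillment, total_loss,
#'   storage_loss, transport_loss, expiration_loss, breakage_loss,
#'   entered_kg, iterations).
#' @export
scenario_summary <- function(scenarios) {
  if (inherits(scenarios, "veg_scenario")) scenarios <- list(scenarios)
  rows <- lapply(scenarios, function(sc) {
    per_iter <- lapply(sc$results, function(res) {
      ls <- loss_summary(res)
      ful <- res$tallies |>
        dplyr::filter(.data$level %in% c("retailer", "surrogate_retail")) |>
        dplyr::group_by(.data$crop) |>
        dplyr::summarise(
          retail_fulfillment = ifelse(sum(.data$arrivals) > 0,
                                      sum(.data$fulfilled) /
                                        sum(.data$arrivals), NA_real_),
          .groups = "drop")
      dplyr::left_join(ful, ls, by = "crop")
    })
    dplyr::bind_rows(per_iter) |>
      dplyr::group_by(.data$crop) |>
      dplyr::summarise(dplyr::across(dplyr::everything(),
                                     ~ mean(.x, na.rm = TRUE)),
                       .groups = "drop") |>
      dplyr::mutate(multiplier = sc$config$production_multiplier,
                    iterations = length(sc$results))
  })
  dplyr::bind_rows(rows) |>
    dplyr::relocate("multiplier") |>
    dplyr::arrange(.data$multiplier, .data$crop)
}

#' @export
tidy.veg_sim <- function(x, ...) {
  ls <- loss_summary(x)
  ful <- x$tallies |>
    dplyr::group_by(.data$crop) |>
    dplyr::summarise(
      retail_fulfillment = fulfillment_or_na(
        .data$fulfilled[.data$level %in% c("retailer", "surrogate_retail")],
        .data$arrivals[.data$level %in% c("retailer", "surrogate_retail")]),
      overall_fulfillment = fulfillment_or_na(.data$fulfilled,
                                              .data$arrivals),
      .groups = "drop")
  tc <- dplyr::select(x$chain_time, "crop", "mean_days", "max_days")
  ful |>
    dplyr::left_join(ls, by = "crop") |>
    dplyr::left_join(tc, by = "crop")
}

fulfillment_or_na <- function(fulfilled, arrivals) {
  if (sum(arrivals) == 0) return(NA_real_)
  sum(fulfilled) / sum(arrivals)
}

#' @export
glance.veg_sim <- function(x, ...) {
  f <- x$flows
  entered <- sum(f$entered_production_kg + f$entered_import_kg)
  tibble::tibble(
    crops = nrow(f),
    days = x$config$horizon,
    multiplier = x$config$production_multiplier,
    entered_kg = entered,
    purchased_kg = sum(f$purchased_kg),
    exported_kg = sum(f$exported_kg),
    total_loss = sum(f$expired_kg + f$broken_kg) / entered,
    retail_fulfillment = fulfillment_or_na(
      x$tallies$fulfilled[x$tallies$level %in%
                            c("retailer", "surrogate_retail")],
      x$tallies$arrivals[x$tallies$level %in%
                           c("retailer", "surrogate_retail")]),
    max_balance_rel = max(mass_balance_residual(x)$relative))
}

#' Plot availability and losses against the production multiplier
#'
#' @param summary A [scenario_summary()] table.
#' @return A ggplot: demand fulfillment (top) and total loss with its
#'   storage/transport split (bottom), by crop.
#' @export
plot_scenario_summary <- function(summary) {
  long <- summary |>
    dplyr::select("multiplier", "crop", "retail_fulfillment",
                  "storage_loss", "transport_loss") |>
    tidyr::pivot_longer(c("retail_fulfillment", "storage_loss",
                          "transport_loss"),
                        names_to = "measure", values_to = "value") |>
    dplyr::mutate(panel = ifelse(.data$measure == "retail_fulfillment",
                                 "Retail demand fulfillment", "Total loss"))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$multiplier),
                                     y = .data$value,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_grid(panel ~ crop, scales = "free_y") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%",
                                                             100 * v)) +
    ggplot2::labs(x = "production multiplier", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot loss composition by supply chain stage
#'
#' @param result A `veg_sim`.
#' @return A ggplot of per-crop loss fractions stacked by stage.
#' @export
plot_loss_stages <- function(result) {
  lb <- loss_breakdown(result) |>
    dplyr::group_by(.data$crop, .data$stage) |>
    dplyr::summarise(frac = sum(.data$frac_of_entered), .groups = "drop") |>
    dplyr::mutate(stage = factor(.data$stage, levels = STAGES))
  ggplot2::ggplot(lb, ggplot2::aes(x = .data$crop, y = .data$frac,
                                   fill = .data$stage)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%",
                                                             100 * v)) +
    ggplot2::labs(x = NULL, y = "share of entered mass lost", fill = "stage") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.veg_sim <- function(object, ...) plot_loss_stages(object)
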