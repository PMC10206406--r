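MONTH_DAYS_FOR_TEST <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

test_that("seasonal weights normalise to a unit yearly mean", {
  uni <- default_crops()[1, ]
  uni[paste0("m", 1:12)] <- 1
  expect_equal(seasonal_weight(uni, 1:12), rep(1, 12))

  spike <- uni
  spike[paste0("m", 1:12)] <- as.list(c(rep(0, 11), 12))
  expect_equal(seasonal_weight(spike, 12), 12)
  expect_equal(seasonal_weight(spike, 3), 0)

  ragged <- uni
  ragged[paste0("m", 1:12)] <- as.list(runif(12))
  expect_equal(mean(seasonal_weight(ragged, 1:12)), 1)

  zero <- uni
  zero[paste0("m", 1:12)] <- 0
  expect_error(seasonal_weight(zero, 1), "all-zero")
})

test_that("the supply plan balances production, imports and exports monthly", {
  net <- small_network()
  plan <- build_supply_plan(net, default_crops())
  bal <- dplyr::left_join(
    dplyr::summarise(dplyr::group_by(plan$entries, crop, month),
                     prod = sum(rate_kg_d), .groups = "drop"),
    plan$imports, by = c("crop", "month")) |>
    dplyr::left_join(plan$exports, by = c("crop", "month"),
                     suffix = c("_imp", "_exp")) |>
    dplyr::left_join(plan$demand, by = "crop")
  supply <- bal$prod + bal$rate_kg_d_imp - bal$rate_kg_d_exp
  expect_true(all(abs(supply - bal$statewide_kg_d) <
                    1e-6 * bal$statewide_kg_d))
})

test_that("off-season deficits import; structural surplus exports", {
  net <- small_network()
  crops <- default_crops()
  plan <- build_supply_plan(net, crops)
  # potato-like crop harvested 3 months: imports equal full demand in the
  # other 9 months
  pot_d <- plan$demand$statewide_kg_d[plan$demand$crop == "potato"]
  pot_imp <- plan$imports[plan$imports$crop == "potato", ]
  expect_equal(pot_imp$rate_kg_d[!pot_imp$month %in% 1:3], rep(pot_d, 9))
  # brinjal produced at 5.2x demand, uniform season: exports 4.2x demand
  bri_d <- plan$demand$statewide_kg_d[plan$demand$crop == "brinjal"]
  bri_exp <- plan$exports$rate_kg_d[plan$exports$crop == "brinjal"]
  expect_equal(bri_exp, rep(4.2 * bri_d, 12), tolerance = 1e-9)
})

test_that("imports require a Tier 1 entry market", {
  loc <- toy_locations()
  loc$tier[loc$level == "wholesale_market"] <- 2L
  net <- assign_nearest_partners(loc)
  expect_error(build_supply_plan(net, default_crops()), "Tier 1")
})

test_that("daily entries scale exactly with the multiplier at fixed seed", {
  plan <- build_supply_plan(small_network(), default_crops())
  s1 <- make_rng_streams(5, "supply")$supply
  s2 <- make_rng_streams(5, "supply")$supply
  e1 <- daily_entries(plan, day = 40, multiplier = 1, sigma = 0.1,
                      stream = s1)
  e2 <- daily_entries(plan, day = 40, multiplier = 2, sigma = 0.1,
                      stream = s2)
  expect_equal(e2$mass_kg, 2 * e1$mass_kg)
})

test_that("without noise, entries equal plan rate times seasonal weight", {
  net <- small_network()
  crops <- default_crops()
  plan <- build_supply_plan(net, crops)
  e <- daily_entries(plan, day = 1, multiplier = 1, sigma = 0)
  m1 <- plan$entries[plan$entries$month == 1, ]
  expect_equal(e$mass_kg, m1$rate_kg_d)
  # and the monthly plan rate is the annual base scaled by the weight
  cr <- crops[crops$name == "potato", ]
  w <- seasonal_weight(cr, 1)
  annual_base <- sum(plan$entries$rate_kg_d[plan$entries$crop == "potato" &
                                              plan$entries$month == 1]) / w
  expect_equal(annual_base,
               cr$production_ratio *
                 plan$demand$statewide_kg_d[plan$demand$crop == "potato"])
})

test_that("lognormal day noise has unit mean: annual totals match the plan", {
  plan <- build_supply_plan(small_network(), default_crops())
  planned_annual <- sum(plan$entries$rate_kg_d *
                          MONTH_DAYS_FOR_TEST[plan$entries$month])
  s <- make_rng_streams(17, "supply")$supply
  totals <- vapply(1:10, function(i) {
    sum(vapply(1:365, function(d) {
      sum(daily_entries(plan, d, 1, sigma = 0.1, stream = s)$mass_kg)
    }, 0))
  }, 0)
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - planned_annual), 3 * se)
})

test_that("calendar months cover a 365-day year and wrap", {
  expect_equal(month_of_day(1), 1L)
  expect_equal(month_of_day(31), 1L)
  expect_equal(month_of_day(32), 2L)
  expect_equal(month_of_day(365), 12L)
  expect_equal(month_of_day(366), 1L)
  expect_equal(sum(table(month_of_day(1:365))), 365L)
})
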