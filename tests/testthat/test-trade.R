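test_that("haversine distance matches the sphere geometry", {
  expect_equal(haversine_km(12.3, 45.6, 12.3, 45.6), 0)
  # one degree of longitude on the equator: 2*pi*6371/360
  expect_equal(haversine_km(0, 0, 0, 1), 2 * pi * 6371 / 360,
               tolerance = 1e-6)
  expect_equal(haversine_km(19.2, 84.1, 21.7, 86.3),
               haversine_km(21.7, 86.3, 19.2, 84.1))
})

test_that("nearest-partner assignment picks closest, ties by lowest id", {
  loc <- tibble::tibble(
    id = c("V001", "W001", "W002"),
    level = c("village_market", "wholesale_market", "wholesale_market"),
    tier = c(NA, 1L, 1L),
    lat = c(20, 20, 20),
    lon = c(85, 85.05, 85.10), # W001 ~5 km away, W002 ~10 km
    population = c(1000, 1000, 1000),
    direct_sale_fraction = 0.05, storage_volume_m3 = Inf, arrival_hour = 10)
  net <- assign_nearest_partners(loc)
  vr <- net$routes[net$routes$origin == "V001", ]
  expect_equal(vr$destination, "W001")

  # equidistant wholesale markets: lowest id wins
  loc$lon <- c(85, 85.05, 84.95)
  net2 <- assign_nearest_partners(loc)
  expect_equal(net2$routes$destination[net2$routes$origin == "V001"], "W001")

  expect_error(assign_nearest_partners(loc[1, ]), "no wholesale markets")
})

test_that("a generated 50-node network satisfies every invariant", {
  net <- generate_network(generator_params(n_village = 30, n_tier1 = 1,
                                           n_tier2 = 2, n_tier3 = 6,
                                           retailers_per_wholesale = 3,
                                           seed = 21))
  expect_equal(nrow(validate_network(net)), 0L)
  # tier 1/2 complete graph + one edge per tier 3 market
  expect_equal(nrow(net$partners), choose(3, 2) + 6)
})

test_that("compute_order implements order-up-to and fixed-quantity modes", {
  pol <- list(quantity_mode = "variable", review_period_d = 1,
              safety_stock_d = 1, fixed_quantity_kg = NA_real_)
  est <- tibble::tibble(daily_demand_kg = 100, on_hand_kg = 50,
                        in_transit_kg = 0)
  expect_equal(compute_order(pol, est), 150)
  est$on_hand_kg <- 500 # amply covered
  expect_equal(compute_order(pol, est), 0)

  fixed <- list(quantity_mode = "fixed", review_period_d = 1,
                safety_stock_d = 0, fixed_quantity_kg = 75)
  expect_equal(compute_order(fixed, tibble::tibble(
    daily_demand_kg = 100, on_hand_kg = 200, in_transit_kg = 0)), 0)
  expect_equal(compute_order(fixed, tibble::tibble(
    daily_demand_kg = 100, on_hand_kg = 20, in_transit_kg = 0)), 75)
})

test_that("lateral transfers respect deficits, surpluses and partnerships", {
  partners <- tibble::tibble(a = "A", b = "B")
  balanced <- tibble::tibble(
    market = c("A", "B", "C"), crop = "tomato",
    daily_demand_kg = 100, on_hand_kg = 150, in_transit_kg = 0)
  expect_equal(nrow(lateral_transfers(partners, balanced)), 0L)

  est <- tibble::tibble(
    market = c("A", "B"), crop = "tomato",
    daily_demand_kg = c(100, 200),
    on_hand_kg = c(600, 0), in_transit_kg = 0)
  tr <- lateral_transfers(partners, est)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$from, "A")
  expect_equal(tr$to, "B")
  expect_equal(tr$quantity_kg, 200)

  # B in deficit but only non-partner C holds surplus: no transfer
  est3 <- tibble::tibble(
    market = c("A", "B", "C"), crop = "tomato",
    daily_demand_kg = c(100, 200, 100),
    on_hand_kg = c(100, 0, 900), in_transit_kg = 0)
  expect_equal(nrow(lateral_transfers(partners, est3)), 0L)

  # a sender is never drawn below one day of its own demand
  est4 <- tibble::tibble(
    market = c("A", "B"), crop = "tomato",
    daily_demand_kg = c(100, 500),
    on_hand_kg = c(130, 0), in_transit_kg = 0)
  tr4 <- lateral_transfers(partners, est4)
  expect_equal(tr4$quantity_kg, 30)
})

test_that("orders depend only on a market's own state and direct partners", {
  partners <- tibble::tibble(a = c("A", "C"), b = c("B", "D"))
  est <- tibble::tibble(
    market = c("A", "B", "C", "D"), crop = "onion",
    daily_demand_kg = c(100, 100, 100, 100),
    on_hand_kg = c(700, 10, 400, 10), in_transit_kg = 0)
  tr1 <- lateral_transfers(partners, est)
  perturbed <- est
  perturbed$on_hand_kg[perturbed$market == "C"] <- 5000 # not A/B's partner
  tr2 <- lateral_transfers(partners, perturbed)
  expect_identical(tr1[tr1$to == "B", ], tr2[tr2$to == "B", ])
})

test_that("vehicle loading prioritises perishability and conserves mass", {
  crops <- default_crops()
  # everything fits
  lots <- lot_tibble(c("potato", "brinjal"), c(650, 350), c(0, 0), c(0, 0))
  all_in <- load_vehicle(lots, 10, crops)
  expect_equal(sum(all_in$loaded$mass_kg), 1000)
  expect_equal(nrow(all_in$left_behind), 0L)

  # room for one of {brinjal (4 d), potato (21 d)}: brinjal goes
  tight <- load_vehicle(lots, 1, crops)
  expect_true("brinjal" %in% tight$loaded$crop)
  expect_false("potato" %in% tight$loaded$crop[
    tight$loaded$mass_kg > 1e-9])

  # 650 kg of potato at 650 kg/m3 occupies exactly 1 m3
  pot <- lot_tibble("potato", 650, 0, 0)
  expect_equal(nrow(load_vehicle(pot, 1, crops)$left_behind), 0L)
  just_under <- load_vehicle(lot_tibble("potato", 651, 0, 0), 1, crops)
  expect_equal(sum(just_under$loaded$mass_kg), 650)
  expect_equal(sum(just_under$left_behind$mass_kg), 1)

  # boundary lot splits; loaded + left behind equals input exactly
  mix <- lot_tibble(c("brinjal", "tomato", "potato"), c(200, 300, 400),
                    c(1, 0.5, 2), c(0, 0, 0))
  sp <- load_vehicle(mix, 1.0, crops)
  expect_equal(sum(sp$loaded$mass_kg) + sum(sp$left_behind$mass_kg),
               sum(mix$mass_kg))
  vol <- sum(sp$loaded$mass_kg /
               setNames(crops$density_kg_m3, crops$name)[sp$loaded$crop])
  expect_equal(vol, 1.0, tolerance = 1e-9)
  # within a crop, older lots load first
  same <- lot_tibble(c("tomato", "tomato"), c(300, 300), c(0.5, 3), c(0, 0))
  half <- load_vehicle(same, 0.5, crops)
  expect_equal(half$loaded$effective_age_d, 3)
})
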