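test_that("events pop in time order regardless of insertion order", {
  q <- new_event_queue()
  schedule_event(q, 2, "consumer_arrival", "b")
  schedule_event(q, 1, "consumer_arrival", "a")
  schedule_event(q, 5, "consumer_arrival", "c")
  expect_equal(next_event(q)$payload, "a")
  expect_equal(next_event(q)$payload, "b")
  expect_equal(next_event(q)$payload, "c")
  expect_null(next_event(q))
})

test_that("same-instant ties follow the fixed kind priority", {
  # arrivals before departures before reviews before consumer arrivals,
  # so goods landing at time t are sellable at time t
  q <- new_event_queue()
  schedule_event(q, 3, "consumer_arrival")
  schedule_event(q, 3, "daily_review")
  schedule_event(q, 3, "vehicle_departure")
  schedule_event(q, 3, "vehicle_arrival")
  kinds <- c(next_event(q)$kind, next_event(q)$kind, next_event(q)$kind,
             next_event(q)$kind)
  expect_equal(kinds, c("vehicle_arrival", "vehicle_departure",
                        "daily_review", "consumer_arrival"))
})

test_that("equal time and kind preserves insertion order", {
  q <- new_event_queue()
  for (i in 1:20) schedule_event(q, 1, "consumer_arrival", i)
  expect_equal(vapply(1:20, function(i) next_event(q)$payload, 0), 1:20)
})

test_that("scheduling in the past or with an unknown kind is an error", {
  q <- new_event_queue()
  schedule_event(q, 4, "daily_review")
  invisible(next_event(q)) # clock now 4
  expect_error(schedule_event(q, 3, "daily_review"), "past")
  expect_error(schedule_event(q, 5, "lunch_break"), "unknown event kind")
})

test_that("rng streams are deterministic functions of (seed, label)", {
  s1 <- make_rng_streams(11, c("breakage", "arrivals"))
  s2 <- make_rng_streams(11, c("breakage", "arrivals"))
  expect_identical(rs_unif(s1$breakage, 100), rs_unif(s2$breakage, 100))
  expect_false(identical(rs_unif(s1$breakage, 10), rs_unif(s1$arrivals, 10)))
  expect_error(make_rng_streams(1, c("a", "a")), "unique")
  # label alone determines the stream, not its position in the list
  s3 <- make_rng_streams(11, c("arrivals", "breakage", "extra"))
  s4 <- make_rng_streams(11, "breakage")
  expect_identical(rs_unif(s3$breakage, 50), rs_unif(s4$breakage, 50))
})

test_that("paired draws across two labels are uncorrelated", {
  s <- make_rng_streams(202, c("u", "v"))
  n <- 1e5
  r <- cor(rs_unif(s$u, n), rs_unif(s$v, n))
  expect_lt(abs(r), 3 / sqrt(n))
})

test_that("drawing from a stream leaves the global RNG state alone", {
  set.seed(99)
  before <- .Random.seed
  s <- make_rng_streams(1, "x")
  invisible(rs_pois(s$x, 10, 2))
  expect_identical(.Random.seed, before)
})

test_that("a zero-day horizon yields a result with zero tallies", {
  res <- run_simulation(toy_network(), default_crops(),
                        scenario_config(horizon = 0, burn_in = 1,
                                        iterations = 1, seed = 1))
  expect_equal(nrow(res$tallies), 0L)
  expect_equal(sum(res$flows$entered_production_kg), 0)
  expect_equal(sum(res$losses$mass_kg), 0)
})

test_that("the same inputs and seed reproduce the result exactly", {
  cfg <- scenario_config(horizon = 8, burn_in = 2, iterations = 1, seed = 5)
  net <- small_network()
  crops <- default_crops()
  r1 <- run_simulation(net, crops, cfg)
  r2 <- run_simulation(net, crops, cfg)
  expect_identical(r1$tallies, r2$tallies)
  expect_identical(r1$losses, r2$losses)
  expect_identical(r1$flows, r2$flows)
  r3 <- run_simulation(net, crops, cfg, seed = 6)
  expect_false(identical(r1$tallies, r3$tallies))
})

test_that("burn-in days feed state but are excluded from tallies", {
  net <- toy_network()
  crops <- ample_crops()
  cfg <- scenario_config(horizon = 5, burn_in = 4, iterations = 1, seed = 2,
                         entry_noise_sigma = 0)
  res <- run_simulation(net, crops, cfg)
  expect_setequal(unique(res$tallies$day), 1:5)
  # with sigma = 0 the tallied entries are exactly horizon x plan rate
  plan <- build_supply_plan(net, crops)
  daily <- sum(plan$entries$rate_kg_d[plan$entries$month == 1])
  expect_equal(sum(res$flows$entered_production_kg), 5 * daily,
               tolerance = 1e-12)
  # the chain is not empty at the burn-in boundary
  expect_gt(sum(res$flows$start_stock_kg + res$flows$start_intransit_kg), 0)
})

test_that("an invalid network or crop table is refused", {
  net <- toy_network()
  bad <- net$locations
  bad$direct_sale_fraction[1] <- 2
  expect_error(run_simulation(veg_network(bad, net$routes, net$partners),
                              default_crops(), scenario_config(horizon = 1)),
               "invalid network")
  crops <- default_crops()
  crops$lifespan_d[1] <- -1
  expect_error(run_simulation(net, crops, scenario_config(horizon = 1)),
               "invalid crop table")
})
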