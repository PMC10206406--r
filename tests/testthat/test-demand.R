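test_that("arrival counts are Poisson around the direct-sale catchment", {
  s <- make_rng_streams(4, "arrivals")$arrivals
  zero <- tibble::tibble(population = 0, direct_sale_fraction = 0.05)
  expect_equal(consumer_arrival_count(zero, s, 10), rep(0L, 10))

  # a village market serving 390 local consumers on average
  vil <- tibble::tibble(population = 7800, direct_sale_fraction = 0.05)
  n <- 1e4
  draws <- consumer_arrival_count(vil, s, n)
  expect_lt(abs(mean(draws) - 390), 3 * sqrt(390 / n))

  # separate stream labels give independent sequences
  s2 <- make_rng_streams(4, c("arrivals_a", "arrivals_b"))
  expect_false(identical(consumer_arrival_count(vil, s2$arrivals_a, 50),
                         consumer_arrival_count(vil, s2$arrivals_b, 50)))
})

test_that("serve_arrival dispatches FEFO and flags partial service", {
  inv <- lot_tibble(c("tomato", "tomato"), c(0.2, 0.5), c(1, 3), c(10, 5))

  r0 <- serve_arrival(inv, c(tomato = 0))
  expect_true(r0$fulfilled[["tomato"]])
  expect_equal(r0$served_kg[["tomato"]], 0)
  expect_identical(r0$lots, inv)

  # 100 g available, 150 g requested: partial quantity sold, unfulfilled
  short <- lot_tibble("tomato", 0.1, 1, 0)
  r1 <- serve_arrival(short, c(tomato = 150))
  expect_equal(r1$served_kg[["tomato"]], 0.1)
  expect_false(r1$fulfilled[["tomato"]])
  expect_equal(nrow(r1$lots), 0L)

  # the 3-day-old lot is consumed before the 1-day-old lot
  r2 <- serve_arrival(inv, c(tomato = 500))
  expect_true(r2$fulfilled[["tomato"]])
  expect_equal(r2$lots$effective_age_d, 1)
  expect_equal(r2$lots$mass_kg, 0.2)
})

test_that("fulfillment_fraction filters and flags empty scopes", {
  tal <- tibble::tibble(
    crop = c("cabbage", "cabbage", "potato"),
    location = c("R1", "R2", "R1"),
    level = c("retailer", "retailer", "retailer"),
    day = c(1L, 2L, 1L),
    arrivals = c(60L, 40L, 10L),
    fulfilled = c(45L, 27L, 10L),
    purchased_kg = c(1, 1, 1))
  expect_equal(fulfillment_fraction(tal, crop = "potato"), 1)
  expect_equal(fulfillment_fraction(tal, crop = "cabbage"), 0.72)
  expect_equal(fulfillment_fraction(tal, crop = "cabbage", days = c(1, 1)),
               0.75)
  expect_warning(f <- fulfillment_fraction(tal, crop = "onion"),
                 "undefined")
  expect_true(is.na(f))
})

test_that("FEFO losses never exceed any other dispatch order", {
  # 2 lots, 3 arrivals; enumerate every dispatch order by brute force.
  # Lifespan 4 d. Lot A is 3.8 d old (expires at +0.2 d), lot B is 1.0 d
  # old (expires at +3.0 d); arrivals at +0, +0.3 and +2.9 d each want 1 kg.
  crops <- default_crops()[default_crops()$name == "brinjal", ]
  arrivals <- c(0, 0.3, 2.9) * 24 # hours
  base <- lot_tibble(c("brinjal", "brinjal"), c(2, 2), c(3.8, 1.0), c(0, 0))

  run_order <- function(choices) {
    lots <- base
    lots$lot_id <- c("A", "B")
    expired <- 0
    served <- 0
    t <- 0
    for (i in seq_along(arrivals)) {
      lots <- age_lots(lots, arrivals[i] - t)
      t <- arrivals[i]
      r <- remove_expired(lots, crops)
      expired <- expired + sum(r$expired_kg)
      lots <- r$surviving
      pick <- choices[i]
      j <- which(lots$lot_id == pick)
      if (length(j)) {
        take <- min(1, lots$mass_kg[j])
        lots$mass_kg[j] <- lots$mass_kg[j] - take
        served <- served + take
        lots <- lots[lots$mass_kg > 0, ]
      }
    }
    lots <- age_lots(lots, 10 * 24 - t)
    expired + sum(remove_expired(lots, crops)$expired_kg)
  }

  all_orders <- expand.grid(a1 = c("A", "B"), a2 = c("A", "B"),
                            a3 = c("A", "B"), stringsAsFactors = FALSE)
  losses <- apply(all_orders, 1, run_order)

  # the FEFO path through the same trace, via serve_arrival
  lots <- base
  expired_fefo <- 0
  t <- 0
  for (i in seq_along(arrivals)) {
    lots <- age_lots(lots, arrivals[i] - t)
    t <- arrivals[i]
    r <- remove_expired(lots, crops)
    expired_fefo <- expired_fefo + sum(r$expired_kg)
    sv <- serve_arrival(r$surviving, c(brinjal = 1000))
    lots <- sv$lots
  }
  lots <- age_lots(lots, 10 * 24 - t)
  expired_fefo <- expired_fefo + sum(remove_expired(lots, crops)$expired_kg)

  expect_true(all(expired_fefo <= losses + 1e-12))
  expect_equal(expired_fefo, min(losses))
  # newest-first (always pick the youngest lot, B) is strictly worse here
  newest_first <- run_order(c("B", "B", "B"))
  expect_lt(expired_fefo, newest_first)
})
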