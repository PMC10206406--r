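test_that("loss breakdown reproduces a hand-computed trace", {
  # 100 kg entered; 10 kg expired in wholesale storage; 2 kg broken on the
  # village-to-wholesale leg: total 12%, expiration 10%, breakage 2%
  res <- hand_result(entered = 100,
                     expired = c(wholesale_storage = 10),
                     broken = c(village_wholesale_transport = 2),
                     purchased = 88)
  ls <- loss_summary(res)
  expect_equal(ls$total_loss, 0.12)
  expect_equal(ls$expiration_loss, 0.10)
  expect_equal(ls$breakage_loss, 0.02)
  expect_equal(ls$storage_loss, 0.10)
  expect_equal(ls$transport_loss, 0.02)

  zero <- hand_result(entered = 50, purchased = 50)
  expect_true(all(loss_summary(zero)$total_loss == 0))

  none <- hand_result(entered = 0)
  expect_error(loss_breakdown(none), "zero entered mass")
})

test_that("mechanism and stage splits always sum to the total", {
  res <- small_run(seed = 3)
  lb <- loss_breakdown(res)
  by_mech <- tapply(lb$frac_of_entered, lb$crop, sum)
  ls <- loss_summary(res)
  expect_equal(as.numeric(by_mech[ls$crop]), ls$total_loss, tolerance = 1e-12)
  expect_equal(ls$expiration_loss + ls$breakage_loss, ls$total_loss,
               tolerance = 1e-12)
  expect_equal(ls$storage_loss + ls$transport_loss, ls$total_loss,
               tolerance = 1e-12)
  expect_true(all(lb$frac_of_entered >= 0 & lb$frac_of_entered <= 1))
})

test_that("mass balance audits every run and detects corruption", {
  empty <- hand_result(entered = 0)
  expect_equal(mass_balance_residual(empty)$residual_kg, 0)

  res <- small_run(seed = 3)
  mb <- mass_balance_residual(res)
  expect_true(all(mb$relative <= 1e-6))

  corrupted <- res
  corrupted$flows$purchased_kg[2] <- corrupted$flows$purchased_kg[2] + 500
  expect_gt(max(mass_balance_residual(corrupted)$relative), 1e-6)
})

test_that("time-in-chain statistics are mass-weighted", {
  res <- hand_result(entered = 10, purchased = 10)
  res$chain_time <- tibble::tibble(crop = "potato", exited_kg = 10,
                                   mean_days = 2, max_days = 2)
  res$chain_samples <- tibble::tibble(crop = "potato", days = 2,
                                      mass_kg = 10)
  st <- time_in_chain_stats(res)
  expect_equal(st$mean_days, 2)
  expect_equal(st$max_days, 2)
  expect_equal(st$q50, 2)

  # two equal-mass exits at 1 and 3 days: mean 2, max 3
  res$chain_time <- tibble::tibble(crop = "potato", exited_kg = 10,
                                   mean_days = (5 * 1 + 5 * 3) / 10,
                                   max_days = 3)
  res$chain_samples <- tibble::tibble(crop = "potato", days = c(1, 3),
                                      mass_kg = c(5, 5))
  st2 <- time_in_chain_stats(res)
  expect_equal(st2$mean_days, 2)
  expect_equal(st2$max_days, 3)

  none <- hand_result(entered = 5)
  expect_error(time_in_chain_stats(none), "no exits")
})

test_that("simulated chain times are positive and bounded by the run", {
  res <- small_run(seed = 3, horizon = 20)
  st <- time_in_chain_stats(res)
  expect_true(all(st$mean_days > 0))
  expect_true(all(st$max_days <= res$config$burn_in + res$config$horizon))
  expect_true(all(st$mean_days <= st$max_days))
})

test_that("scenario summaries average iterations and track entered mass", {
  net <- small_network()
  crops <- default_crops()
  base <- scenario_config(horizon = 6, burn_in = 2, iterations = 2, seed = 9,
                          entry_noise_sigma = 0)
  suite <- run_suite(net, crops, base, multipliers = c(1, 2))
  s <- scenario_summary(suite)
  expect_equal(nrow(s), 2 * nrow(crops))
  expect_setequal(s$multiplier, c(1, 2))
  expect_true(all(s$iterations == 2))

  # in-state production scales exactly with the multiplier at fixed seeds
  f1 <- suite[[1]]$results[[1]]$flows
  f2 <- suite[[2]]$results[[1]]$flows
  grown <- f1$entered_production_kg > 0
  expect_equal(f2$entered_production_kg[grown],
               2 * f1$entered_production_kg[grown])
  # imports are deliberately not scaled
  expect_equal(f2$entered_import_kg, f1$entered_import_kg)

  single <- scenario_summary(run_scenario(net, crops, base))
  expect_equal(nrow(single), nrow(crops))
})

test_that("tidy and glance give per-crop and whole-run views", {
  res <- small_run(seed = 3)
  td <- tidy(res)
  expect_equal(nrow(td), 5L)
  expect_true(all(c("crop", "retail_fulfillment", "total_loss",
                    "mean_days") %in% names(td)))
  expect_true(all(td$retail_fulfillment >= 0 & td$retail_fulfillment <= 1))
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  expect_lt(gl$max_balance_rel, 1e-6)
})

test_that("plot builders return ggplot objects", {
  res <- small_run(seed = 3)
  expect_s3_class(plot_loss_stages(res), "ggplot")
  expect_s3_class(autoplot(res), "ggplot")
  s <- scenario_summary(run_scenario(small_network(), default_crops(),
                                     scenario_config(horizon = 4,
                                                     burn_in = 2,
                                                     iterations = 1,
                                                     seed = 2)))
  expect_s3_class(plot_scenario_summary(s), "ggplot")
})
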