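# Synthetic generators: determinism, marginal contracts, planted structure.

test_that("generators are pure functions of their seed", {
  m1 <- gen_daily_met(100, seed = 5)
  m2 <- gen_daily_met(100, seed = 5)
  expect_identical(m1, m2)
  expect_false(identical(m1$wind_speed, gen_daily_met(100, seed = 6)$wind_speed))
  a1 <- gen_pm25(m1, seed = 3); a2 <- gen_pm25(m1, seed = 3)
  expect_identical(a1, a2)
  t1 <- gen_activity_table(c("A", "B"), 2013:2014, seed = 2)
  expect_identical(t1, gen_activity_table(c("A", "B"), 2013:2014, seed = 2))
  p1 <- gen_dea_instance(seed = 4); p2 <- gen_dea_instance(seed = 4)
  expect_identical(p1$input_mean, p2$input_mean)
  expect_identical(gen_random_panel(seed = 9)$input_sd,
                   gen_random_panel(seed = 9)$input_sd)
  # generating does not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_daily_met(10, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("degenerate temperature settings give a constant series", {
  p <- default_weather_params()
  p$temperature$phi <- 0; p$temperature$sd <- 0
  met <- gen_daily_met(50, seed = 1, params = p)
  expect_true(all(met$temperature == met$temperature[1]))
  expect_identical(count_temp_change_days(met), 0L)
})

test_that("wet-day frequency matches the configured occurrence probability", {
  met <- gen_daily_met(10000, seed = 42)
  p_wet <- default_weather_params()$precip$p_wet
  expect_lt(abs(mean(met$precipitation > 0) - p_wet), 0.02)
  expect_true(all(met$rh >= 0 & met$rh <= 100))
  expect_true(all(met$wind_speed >= 0))
  expect_true(all(met$precipitation >= 0))
})

test_that("null PM2.5 coupling recovers the baseline exceedance rate", {
  met <- gen_daily_met(10000, seed = 7)
  air <- gen_pm25(met, coupling = rep(0, 5), base_rate = 0.2, seed = 8)
  rate <- mean(air$pm25 > 75)
  # binomial 99.9% band around 0.2 at n = 10000 is about +/- 0.013
  expect_lt(abs(rate - 0.2), 0.015)
})

test_that("positive coupling concentrates pollution days on disaster days", {
  met <- gen_daily_met(10000, seed = 17)
  air <- gen_pm25(met, coupling = rep(1.2, 5), base_rate = 0.05, seed = 18)
  active <- rowSums(cbind(met$wind_speed < 1.5, met$precipitation == 0,
                          c(NA, diff(met$temperature)) > 0,
                          c(NA, diff(met$pressure)) < 0,
                          met$rh >= 60 & met$rh <= 90 & met$precipitation == 0),
                    na.rm = TRUE)
  hi <- air$pm25[active >= 3] > 75
  lo <- air$pm25[active <= 1] > 75
  tst <- prop.test(c(sum(hi), sum(lo)), c(length(hi), length(lo)),
                   alternative = "greater")
  expect_lt(tst$p.value, 1e-6)
})

test_that("planted frontier DMUs are exactly BCC-efficient at zero noise", {
  for (s in 1:5) {
    pan <- gen_dea_instance(n_dmus = 7, m_inputs = 3, n_efficient = 3,
                            noise_cv = 0, seed = s)
    eff <- vapply(seq_len(7), function(o) solve_bcc_output(pan, o)$efficiency, 0)
    planted <- match(pan$meta$planted$efficient, pan$dmu_ids)
    expect_true(all(eff[planted] == 1))
    expect_true(all(eff[-planted] < 1))
  }
})

test_that("the planted influencer is the unique discriminating deletion", {
  pan <- gen_dea_instance(n_dmus = 6, m_inputs = 4, n_efficient = 2,
                          noise_cv = 0, planted_influencer = list(dmu = 4, input = 3),
                          seed = 11)
  inf <- pan$meta$planted$influencer
  expect_identical(inf$dmu, pan$dmu_ids[4])
  expect_identical(inf$input, pan$input_names[3])
  base <- solve_bcc_output(pan, inf$dmu)$efficiency
  expect_equal(base, 1)
  del <- solve_bcc_output(delete_variables(pan, inf$input), inf$dmu)$efficiency
  expect_lt(del, 1 - 1e-4)
  for (v in setdiff(pan$input_names, inf$input)) {
    expect_equal(solve_bcc_output(delete_variables(pan, v), inf$dmu)$efficiency,
                 base, tolerance = 1e-9)
  }
})

test_that("generated panels satisfy the container invariants", {
  for (s in 1:5) {
    pan <- gen_random_panel(n_dmus = 5, m_inputs = 6, seed = s)
    expect_true(all(pan$input_sd >= 0))
    expect_true(all(pan$output_sd >= 0))
    expect_identical(dim(pan$input_mean), dim(pan$input_sd))
    expect_identical(length(pan$input_groups), ncol(pan$input_mean))
    pi2 <- gen_dea_instance(n_dmus = 5, m_inputs = 3, n_efficient = 2,
                            noise_cv = 0.1, seed = s)
    expect_true(all(pi2$input_sd >= 0))
  }
  expect_error(gen_dea_instance(n_dmus = 3, n_efficient = 5),
               class = "hazedea_error")
  expect_error(gen_dea_instance(n_dmus = 3, m_inputs = 1, n_efficient = 2,
                                planted_influencer = list(dmu = 1, input = 1)),
               class = "hazedea_error")
})

test_that("the simulated pipeline runs end to end over many seeds", {
  for (s in 1:10) {
    met <- gen_daily_met(365, seed = s, city = "E")
    air <- gen_pm25(met, seed = s + 1)
    mon <- build_disaster_panel(met, air, by = "month")
    expect_identical(sum(mon$n_observed_days), 365L)
    expect_true(all(mon$pm25_pollution_days <= mon$n_observed_days))
  }
  # and through the DEA stage on a small multi-city bundle
  ids <- sprintf("C%02d", 1:4)
  met <- do.call(rbind, lapply(seq_along(ids), function(ci) {
    gen_daily_met(365, seed = 300 + ci, city = ids[ci])
  }))
  air <- do.call(rbind, lapply(seq_along(ids), function(ci) {
    gen_pm25(met[met$city == ids[ci], ], seed = 350 + ci)
  }))
  mon <- build_disaster_panel(met, air, by = "month")
  act <- gen_activity_table(ids, 2013, seed = 5)
  pan <- build_indicator_panel(mon, act, year = 2013)
  res <- solve_ccdea(pan, 1, 0.9)
  expect_true(res$efficiency > 0 && res$efficiency <= 1)
})
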