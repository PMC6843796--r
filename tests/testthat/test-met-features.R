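# Disaster-point and pollution-day counters.

test_that("threshold counters reproduce the hand-enumerated toy series", {
  met <- toy_met()
  air <- toy_air()
  # winds 1.0, 2.0, 1.4, 1.5, 0.9: the boundary 1.5 m/s does not count
  expect_identical(count_low_wind_days(met), 3L)
  expect_identical(count_low_wind_days(toy_met(wind = c(1.5, 1.6, 2.0),
                                               precip = rep(0, 3),
                                               temp = 1:3, pres = rep(1000, 3),
                                               rh = rep(50, 3))), 0L)
  expect_identical(count_no_precip_days(met), 4L)
  expect_identical(count_no_precip_days(toy_met(precip = rep(2, 5))), 0L)
  # diffs +1, -0.5, +1.5, 0: zero change excluded by strict >
  expect_identical(count_temp_change_days(met), 2L)
  # pressure diffs -2, 0, +3, 0: one strict drop
  expect_identical(count_pressure_change_days(met), 1L)
  # RH 65 and 90 qualify (band inclusive); 70 falls on a precipitation day
  expect_identical(count_rh_band_days(toy_met(precip = c(0, 0, 0, 0, 2))), 2L)
  expect_identical(count_rh_band_days(toy_met(rh = rep(50, 5))), 0L)
  # concentrations 80, 75, 74.9, 100, 76: "exceeds" is strict, 75 excluded
  expect_identical(count_pm25_pollution_days(air), 3L)
  expect_identical(count_pm25_pollution_days(toy_air(pm25 = c(10, 75, 40))), 0L)
})

test_that("monotone change series give N - 1 change days", {
  up <- toy_met(wind = rep(2, 6), precip = rep(0, 6), temp = 1:6,
                pres = 6:1, rh = rep(50, 6))
  expect_identical(count_temp_change_days(up), 5L)
  expect_identical(count_pressure_change_days(up), 5L)
})

test_that("counters validate their inputs", {
  met <- toy_met()
  expect_error(count_low_wind_days(met[0, ]), class = "hazedea_error")
  expect_error(count_low_wind_days(toy_met(wind = c(-1, 1, 1, 1, 1))),
               class = "hazedea_error")
  expect_error(count_temp_change_days(met[1, ]), class = "hazedea_error")
  expect_error(count_rh_band_days(met, lo = 90, hi = 60), class = "hazedea_error")
  two <- rbind(toy_met(city = "A"), toy_met(city = "B"))
  expect_error(count_low_wind_days(two), class = "hazedea_error")
  expect_error(count_pm25_pollution_days(toy_air(pm25 = c(-5, 10, 10))),
               class = "hazedea_error")
})

test_that("counters equal brute-force predicate filters on random years", {
  for (s in 1:25) {
    met <- gen_daily_met(365, seed = s)
    air <- gen_pm25(met, seed = s + 1000)
    oc <- oracle_counts(met, air)
    expect_identical(count_low_wind_days(met), oc$ws)
    expect_identical(count_no_precip_days(met), oc$npd)
    expect_identical(count_temp_change_days(met), oc$ptc)
    expect_identical(count_pressure_change_days(met), oc$npc)
    expect_identical(count_rh_band_days(met), oc$rh)
    expect_identical(count_pm25_pollution_days(air), oc$pm)
  }
})

test_that("change-day counters satisfy the partition identity", {
  for (s in 1:5) {
    met <- gen_daily_met(200, seed = s)
    n <- nrow(met)
    nonpos_temp <- sum(diff(met$temperature) <= 0)
    nonneg_pres <- sum(diff(met$pressure) >= 0)
    expect_identical(count_temp_change_days(met) + nonpos_temp, n - 1L)
    expect_identical(count_pressure_change_days(met) + nonneg_pres, n - 1L)
  }
})

test_that("counts are invariant to record order", {
  met <- gen_daily_met(120, seed = 9)
  air <- gen_pm25(met, seed = 10)
  perm <- sample(nrow(met))
  expect_identical(count_temp_change_days(met[perm, ]),
                   count_temp_change_days(met))
  expect_identical(count_low_wind_days(met[perm, ]), count_low_wind_days(met))
  expect_identical(count_pm25_pollution_days(air[sample(nrow(air)), ]),
                   count_pm25_pollution_days(air))
})

test_that("the AQI-qualified pollution-day rule tightens the count", {
  met <- gen_daily_met(365, seed = 3)
  air <- gen_pm25(met, seed = 4)
  base <- count_pm25_pollution_days(air)
  joint <- count_pm25_pollution_days(air, require_aqi = TRUE)
  expect_lte(joint, base)
  # categories derived from PM2.5 alone agree exactly with the threshold
  expect_identical(joint, base)
})

test_that("build_disaster_panel composes the counters", {
  met <- toy_met()
  air <- toy_air()
  expect_warning(pan <- build_disaster_panel(met, air), "observed")
  expect_identical(nrow(pan), 1L)
  expect_identical(pan$ws_days, 3L)
  expect_identical(pan$npd_days, 4L)
  expect_identical(pan$ptc_days, 2L)
  expect_identical(pan$npc_days, 1L)
  expect_identical(pan$rh_days, 2L)
  expect_identical(pan$pm25_pollution_days, 3L)
  expect_identical(pan$n_observed_days, 5L)
})

test_that("a leap-year series reports 366 observed days", {
  met <- gen_daily_met(366, seed = 2, start = as.Date("2016-01-01"))
  air <- gen_pm25(met, seed = 5)
  pan <- build_disaster_panel(met, air)
  expect_identical(pan$n_observed_days, 366L)
  expect_identical(pan$year, 2016L)
})

test_that("annual rows equal independent recomputation and monthly rows sum to them", {
  met <- gen_daily_met(365, seed = 77)
  air <- gen_pm25(met, seed = 78)
  ann <- build_disaster_panel(met, air)
  oc <- oracle_counts(met, air)
  expect_identical(ann$ws_days, oc$ws)
  expect_identical(ann$rh_days, oc$rh)
  expect_identical(ann$pm25_pollution_days, oc$pm)
  mon <- build_disaster_panel(met, air, by = "month")
  expect_identical(nrow(mon), 12L)
  for (v in c("ws_days", "npd_days", "ptc_days", "npc_days", "rh_days",
              "pm25_pollution_days", "n_observed_days")) {
    expect_identical(sum(mon[[v]]), ann[[v]], info = v)
  }
})

test_that("incomplete coverage warns and mismatched cities error", {
  met <- gen_daily_met(100, seed = 1)
  air <- gen_pm25(met, seed = 2)
  expect_warning(build_disaster_panel(met, air), "observed")
  air2 <- air; air2$city <- "other"
  expect_error(suppressWarnings(build_disaster_panel(met, air2)),
               class = "hazedea_error")
})

test_that("CSV round trip preserves the daily records", {
  met <- gen_daily_met(40, seed = 12)
  air <- gen_pm25(met, seed = 13)
  fm <- tempfile(fileext = ".csv"); fa <- tempfile(fileext = ".csv")
  write.csv(met, fm, row.names = FALSE)
  write.csv(air, fa, row.names = FALSE)
  m2 <- read_met_csv(fm); a2 <- read_air_csv(fa)
  expect_equal(m2$wind_speed, met$wind_speed)
  expect_equal(a2$pm25, air$pm25)
  expect_identical(count_rh_band_days(m2), count_rh_band_days(met))
  unlink(c(fm, fa))
})
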