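# Indicator-panel assembly and variable deletion.

test_that("summarize_variable gives textbook sample moments", {
  s <- summarize_variable(c(30, 40, 50))
  expect_equal(s$mean, 40)
  expect_equal(s$sd, 10)
  expect_warning(s1 <- summarize_variable(7), "single")
  expect_equal(s1$mean, 7)
  expect_equal(s1$sd, 0)
  expect_error(summarize_variable(numeric(0)), class = "hazedea_error")
  set.seed(11)
  s2 <- summarize_variable(rnorm(1000, 5, 2))
  expect_lt(abs(s2$mean - 5), 0.2)
  expect_lt(abs(s2$sd - 2), 0.2)
})

make_sources <- function(cities = 4, years = 2013, seed = 1) {
  ids <- sprintf("C%02d", seq_len(cities))
  met <- list(); air <- list()
  for (ci in seq_along(ids)) {
    for (yi in seq_along(years)) {
      m <- gen_daily_met(365, seed = seed + 100 * ci + yi, city = ids[ci],
                         start = as.Date(sprintf("%d-01-01", years[yi])))
      met[[length(met) + 1]] <- m
      air[[length(air) + 1]] <- gen_pm25(m, seed = seed + 100 * ci + yi + 7)
    }
  }
  list(met = do.call(rbind, met), air = do.call(rbind, air),
       activity = gen_activity_table(ids, years, seed = seed))
}

test_that("the monthly strategy yields the full 14-input panel shape", {
  src <- make_sources(cities = 13)
  mon <- build_disaster_panel(src$met, src$air, by = "month")
  pan <- build_indicator_panel(mon, src$activity, year = 2013,
                               sd_strategy = "monthly")
  expect_s3_class(pan, "indicator_panel")
  expect_identical(dim(pan$input_mean), c(13L, 14L))
  expect_identical(dim(pan$output_mean), c(13L, 1L))
  expect_identical(unname(pan$input_groups[c("WS", "GOVIE", "UR", "CCO", "EC", "GCRBA")]),
                   c("MF", "ID", "SP", "T", "EU", "EP"))
  expect_true(all(pan$input_sd >= 0))
  # annualization: mean is 12 x monthly mean = the annual total
  ann <- build_disaster_panel(src$met, src$air, by = "year")
  c1 <- ann[ann$city == "C01", ]
  expect_equal(unname(pan$input_mean["C01", "WS"]), c1$ws_days)
  m1 <- mon[mon$city == "C01", ]
  expect_equal(unname(pan$input_sd["C01", "WS"]), sqrt(12) * sd(m1$ws_days))
  # activity SDs are the configured coefficient of variation
  expect_equal(unname(pan$input_sd["C01", "GOVIE"]),
               0.05 * unname(pan$input_mean["C01", "GOVIE"]))
})

test_that("zero-sd strategy produces the deterministic panel", {
  src <- make_sources(cities = 3)
  ann <- build_disaster_panel(src$met, src$air, by = "year")
  pan <- build_indicator_panel(ann, src$activity, year = 2013,
                               sd_strategy = "zero-sd")
  expect_true(all(pan$input_sd == 0))
  expect_true(all(pan$output_sd == 0))
})

test_that("across-years cells equal summarize_variable over that city's values", {
  src <- make_sources(cities = 3, years = 2013:2016)
  ann <- build_disaster_panel(src$met, src$air, by = "year")
  pan <- build_indicator_panel(ann, src$activity, sd_strategy = "across-years")
  for (ct in c("C01", "C03")) {
    v <- ann$ws_days[ann$city == ct]
    expect_equal(unname(pan$input_mean[ct, "WS"]), mean(v))
    expect_equal(unname(pan$input_sd[ct, "WS"]), sd(v))
    a <- src$activity$TCC[src$activity$city == ct]
    expect_equal(unname(pan$input_mean[ct, "TCC"]), mean(a))
    expect_equal(unname(pan$input_sd[ct, "TCC"]), sd(a))
    p <- ann$pm25_pollution_days[ann$city == ct]
    expect_equal(unname(pan$output_mean[ct, 1]), mean(p))
  }
})

test_that("missing sources are reported in one aggregated error", {
  src <- make_sources(cities = 3)
  mon <- build_disaster_panel(src$met, src$air, by = "month")
  act <- src$activity[src$activity$city != "C02", ]
  err <- tryCatch(build_indicator_panel(mon, act, year = 2013),
                  error = function(e) conditionMessage(e))
  expect_match(err, "different cities")
  act2 <- src$activity[, setdiff(names(src$activity), c("EC", "TCC"))]
  err2 <- tryCatch(build_indicator_panel(mon, act2, year = 2013),
                   error = function(e) conditionMessage(e))
  expect_match(err2, "EC")
  expect_match(err2, "TCC")
})

test_that("deleting groups and singles removes exactly their columns", {
  pan <- gen_random_panel(seed = 1)
  no_mf <- delete_variables(pan, "MF")
  expect_identical(length(no_mf$input_names), 9L)
  expect_false(any(c("WS", "NPD", "PTC", "NPC", "RH") %in% no_mf$input_names))
  no_ws <- delete_variables(pan, "WS")
  expect_identical(length(no_ws$input_names), 13L)
  expect_identical(no_ws$dmu_ids, pan$dmu_ids)
  expect_error(delete_variables(pan, "XX"), class = "hazedea_error")
  expect_error(delete_variables(pan, unique(pan$input_groups)),
               class = "hazedea_error")
  # deleted columns are untouched copies: removing then comparing to the
  # original source restricted to the kept columns
  keep <- no_mf$input_names
  expect_identical(no_mf$input_mean, pan$input_mean[, keep])
  expect_identical(no_mf$input_sd, pan$input_sd[, keep])
})

test_that("column scaling propagates linearly to panel mean and SD", {
  src <- make_sources(cities = 3)
  mon <- build_disaster_panel(src$met, src$air, by = "month")
  p1 <- build_indicator_panel(mon, src$activity, year = 2013)
  act2 <- src$activity
  act2$TCC <- act2$TCC * 3
  p2 <- build_indicator_panel(mon, act2, year = 2013)
  expect_equal(p2$input_mean[, "TCC"], 3 * p1$input_mean[, "TCC"])
  expect_equal(p2$input_sd[, "TCC"], 3 * p1$input_sd[, "TCC"])
  expect_equal(p2$input_mean[, "WS"], p1$input_mean[, "WS"])
})

test_that("panel construction is deterministic and round-trips through disk", {
  src <- make_sources(cities = 3)
  mon <- build_disaster_panel(src$met, src$air, by = "month")
  p1 <- build_indicator_panel(mon, src$activity, year = 2013)
  p2 <- build_indicator_panel(mon, src$activity, year = 2013)
  expect_identical(p1$input_mean, p2$input_mean)
  pre <- tempfile()
  write_indicator_panel(p1, pre)
  p3 <- read_indicator_panel(pre)
  expect_equal(p3$input_mean, p1$input_mean)
  expect_equal(p3$input_sd, p1$input_sd)
  expect_identical(p3$input_groups, p1$input_groups)
  unlink(paste0(pre, c("_means.csv", "_sds.csv", "_meta.json")))
})
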