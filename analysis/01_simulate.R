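#!/usr/bin/env Rscript
# Step 1 - simulate the study inputs.
#
# The original study draws on daily station weather, daily PM2.5 monitoring
# and yearbook indicators for the 13 Jiangsu cities; none of those sources
# are redistributable, so the workflow runs on the package's seeded
# generators instead: AR(1) temperature and pressure, Weibull wind,
# Bernoulli-gamma precipitation, humidity tied to wet days, PM2.5 whose
# exceedance odds rise with the number of active disaster-point conditions,
# and a 9-indicator human-activity table.

library(hazedea)

seed <- 1L
year <- 2013L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cities <- jiangsu_cities()
met <- list(); air <- list()
for (ci in seq_along(cities)) {
  m <- gen_daily_met(365, seed = seed * 1000L + ci, city = cities[ci],
                     start = as.Date(sprintf("%d-01-01", year)))
  met[[ci]] <- m
  air[[ci]] <- gen_pm25(m, seed = seed * 1000L + ci + 500L)
}
met <- do.call(rbind, met)
air <- do.call(rbind, air)
activity <- gen_activity_table(cities, year, seed = seed * 1000L + 999L)

write.csv(met, file.path(out, "daily_met.csv"), row.names = FALSE)
write.csv(air, file.path(out, "daily_pm25.csv"), row.names = FALSE)
write.csv(activity, file.path(out, "activity.csv"), row.names = FALSE)

cat(sprintf("simulated %d city-days of weather and PM2.5 for %d cities\n",
            nrow(met) / length(cities), length(cities)))
cat(sprintf("overall PM2.5 pollution-day rate: %.1f%%\n",
            100 * mean(air$pm25 > 75)))
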