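#!/usr/bin/env Rscript
# Step 2 - threshold feature extraction and the grey relational screen.
#
# Converts the daily series into annual and monthly "disaster point" day
# counts (wind < 1.5 m/s, no precipitation, day-over-day temperature rise,
# day-over-day pressure drop, RH 60-90% on dry days) and PM2.5 pollution
# days (24-h mean > 75 ug/m3), then screens each disaster series against
# the pollution-day series with Deng's grey relational grade across cities.

library(hazedea)

met <- read_met_csv("results/data/daily_met.csv")
air <- read_air_csv("results/data/daily_pm25.csv")

annual <- build_disaster_panel(met, air, by = "year")
monthly <- build_disaster_panel(met, air, by = "month")
write.csv(annual, "results/disaster_annual.csv", row.names = FALSE)
write.csv(monthly, "results/disaster_monthly.csv", row.names = FALSE)

cat("annual disaster-point day counts (range across cities):\n")
for (v in c("ws_days", "npd_days", "ptc_days", "npc_days", "rh_days",
            "pm25_pollution_days")) {
  cat(sprintf("  %-22s %3d .. %3d\n", v, min(annual[[v]]), max(annual[[v]])))
}

grey <- grey_relational_table(annual)
write.csv(grey, "results/grey_relational.csv", row.names = FALSE)
cat("\ngrey relational grades vs pollution days (across cities):\n")
print(grey, row.names = FALSE)
cat("all five disaster-point series clear a grade of",
    sprintf("%.2f", min(grey$grade)), "- kept in the input system\n")
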