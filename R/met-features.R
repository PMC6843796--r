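# Threshold-based feature extraction from daily series: "disaster point" day
# counts (meteorological conditions favourable to PM2.5 accumulation) and
# PM2.5 pollution-day counts.
#
# Disaster-point definitions (all thresholds configurable):
#   WS  - daily mean wind speed strictly below 1.5 m/s
#   NPD - no precipitation (daily total at or below the wet threshold, 0 mm)
#   PTC - positive temperature change: today's mean minus yesterday's > 0
#   NPC - negative pressure change: today's mean minus yesterday's < 0
#   RH  - relative humidity in [60, 90] % on a day with no precipitation
# A PM2.5 pollution day is a day whose 24-h mean concentration strictly
# exceeds 75 ug/m3 (the Chinese GB3095-2012 light-pollution threshold).

met_columns <- c("date", "city", "wind_speed", "precipitation",
                 "temperature", "pressure", "rh")
air_columns <- c("date", "city", "pm25")

#' Read a daily meteorological CSV
#'
#' Expects a header row with columns `date` (ISO-8601), `city`, `wind_speed`
#' (m/s), `precipitation` (mm), `temperature` (degrees C), `pressure` (hPa)
#' and `rh` (%).
#'
#' @param path file path.
#' @return a validated `data.frame` of daily records.
#' @export
read_met_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_met(df)
}

#' Read a daily PM2.5 CSV
#'
#' Expects columns `date` (ISO-8601), `city`, `pm25` (ug/m3) and optionally
#' `aqi_category` (ordinal air-quality class).
#'
#' @param path file path.
#' @return a validated `data.frame` of daily records.
#' @export
read_air_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_air(df)
}

#' @keywords internal
#' @noRd
validate_met <- function(df) {
  if (nrow(df) == 0L) stop_hazedea("empty meteorological series", "empty_series")
  missing <- setdiff(met_columns, names(df))
  if (length(missing)) {
    stop_hazedea(paste("missing meteorological columns:",
                       paste(missing, collapse = ", ")), "bad_columns")
  }
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop_hazedea("unparseable dates", "validation")
  if (anyDuplicated(df[c("city", "date")])) {
    stop_hazedea("duplicate (city, date) rows", "validation")
  }
  if (any(df$wind_speed < 0, na.rm = TRUE)) {
    stop_hazedea("negative wind speed", "validation")
  }
  if (any(df$precipitation < 0, na.rm = TRUE)) {
    stop_hazedea("negative precipitation", "validation")
  }
  if (any(df$rh < 0 | df$rh > 100, na.rm = TRUE)) {
    stop_hazedea("relative humidity outside [0, 100]", "validation")
  }
  if (any(df$pressure <= 0, na.rm = TRUE)) {
    stop_hazedea("non-positive pressure", "validation")
  }
  df[order(df$city, df$date), , drop = FALSE]
}

#' @keywords internal
#' @noRd
validate_air <- function(df) {
  if (nrow(df) == 0L) stop_hazedea("empty air-quality series", "empty_series")
  missing <- setdiff(air_columns, names(df))
  if (length(missing)) {
    stop_hazedea(paste("missing air columns:", paste(missing, collapse = ", ")),
                 "bad_columns")
  }
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop_hazedea("unparseable dates", "validation")
  if (anyDuplicated(df[c("city", "date")])) {
    stop_hazedea("duplicate (city, date) rows", "validation")
  }
  if (any(df$pm25 < 0, na.rm = TRUE)) {
    stop_hazedea("negative PM2.5 concentration", "validation")
  }
  df[order(df$city, df$date), , drop = FALSE]
}

one_city <- function(df, what) {
  if (nrow(df) == 0L) stop_hazedea(paste("empty", what, "series"), "empty_series")
  if (length(unique(df$city)) != 1L) {
    stop_hazedea("records must come from a single city", "validation")
  }
  df[order(df$date), , drop = FALSE]
}

#' Count low-wind days
#'
#' Days whose mean wind speed is strictly below `threshold` (default 1.5 m/s;
#' the boundary value itself does not count).
#'
#' @param met single-city daily meteorological `data.frame`.
#' @param threshold wind-speed threshold in m/s.
#' @return integer day count.
#' @export
count_low_wind_days <- function(met, threshold = 1.5) {
  met <- one_city(met, "meteorological")
  if (any(met$wind_speed < 0)) stop_hazedea("negative wind speed", "validation")
  sum(met$wind_speed < threshold)
}

#' Count no-precipitation days
#'
#' Days with measured precipitation at or below `wet_threshold`. The default
#' treats exactly 0 mm as "no precipitation"; set e.g. `wet_threshold = 0.1`
#' to ignore trace amounts ("no effective precipitation").
#'
#' @param met single-city daily meteorological `data.frame`.
#' @param wet_threshold precipitation threshold in mm.
#' @return integer day count.
#' @export
count_no_precip_days <- function(met, wet_threshold = 0) {
  met <- one_city(met, "meteorological")
  if (any(met$precipitation < 0)) stop_hazedea("negative precipitation", "validation")
  sum(met$precipitation <= wet_threshold)
}

#' Count positive temperature-change days
#'
#' Days (from the second observed day on) whose mean temperature strictly
#' exceeds the previous day's. The first day has no predecessor and
#' contributes nothing; a zero change does not count.
#'
#' @param met single-city daily meteorological `data.frame` with at least
#'   two days.
#' @return integer day count.
#' @export
count_temp_change_days <- function(met) {
  met <- one_city(met, "meteorological")
  if (nrow(met) < 2L) stop_hazedea("need at least two days for change counts", "too_short")
  sum(diff(met$temperature) > 0)
}

#' Count negative pressure-change days
#'
#' Mirror of [count_temp_change_days()]: days whose mean pressure is strictly
#' below the previous day's.
#'
#' @param met single-city daily meteorological `data.frame` with at least
#'   two days.
#' @return integer day count.
#' @export
count_pressure_change_days <- function(met) {
  met <- one_city(met, "meteorological")
  if (nrow(met) < 2L) stop_hazedea("need at least two days for change counts", "too_short")
  sum(diff(met$pressure) < 0)
}

#' Count humid dry days
#'
#' Days with relative humidity in `[lo, hi]` (inclusive at both ends) and no
#' precipitation (at or below `wet_threshold`).
#'
#' @param met single-city daily meteorological `data.frame`.
#' @param lo,hi relative-humidity band bounds in percent.
#' @param wet_threshold precipitation threshold in mm defining a dry day.
#' @return integer day count.
#' @export
count_rh_band_days <- function(met, lo = 60, hi = 90, wet_threshold = 0) {
  if (lo >= hi) stop_hazedea("lo must be strictly below hi", "config")
  met <- one_city(met, "meteorological")
  sum(met$rh >= lo & met$rh <= hi & met$precipitation <= wet_threshold)
}

#' Count PM2.5 pollution days
#'
#' Days whose 24-h mean PM2.5 concentration strictly exceeds `threshold`
#' (default 75 ug/m3; the boundary value does not count). When
#' `require_aqi = TRUE` and an `aqi_category` column is present, a day must
#' additionally be classed lightly polluted or worse. The default rule is
#' concentration-only: a 24-h PM2.5 mean above 75 ug/m3 already places the
#' PM2.5 sub-index above the "good" band, so the joint criterion adds
#' information only when other pollutants drive the reported category.
#'
#' @param air single-city daily PM2.5 `data.frame`.
#' @param threshold concentration threshold in ug/m3.
#' @param require_aqi also require `aqi_category` at or above
#'   "lightly_polluted" (levels: excellent, good, lightly_polluted,
#'   moderately_polluted, heavily_polluted, severely_polluted).
#' @return integer day count.
#' @export
count_pm25_pollution_days <- function(air, threshold = 75, require_aqi = FALSE) {
  air <- one_city(air, "air-quality")
  if (any(air$pm25 < 0)) stop_hazedea("negative PM2.5 concentration", "validation")
  hit <- air$pm25 > threshold
  if (require_aqi) {
    if (is.null(air$aqi_category)) {
      stop_hazedea("require_aqi = TRUE but no aqi_category column", "config")
    }
    lvls <- c("excellent", "good", "lightly_polluted", "moderately_polluted",
              "heavily_polluted", "severely_polluted")
    rank <- match(air$aqi_category, lvls)
    if (anyNA(rank)) stop_hazedea("unknown aqi_category value", "validation")
    hit <- hit & rank >= 3L
  }
  sum(hit)
}

#' Build the disaster-point / pollution-day panel
#'
#' Combines the six day counters into per city-period rows. Change-day
#' counters (temperature, pressure) are computed within each year so the
#' first day of a year never borrows the previous year's value; with
#' `by = "month"` the threshold counters are tallied per month while change
#' days still difference across the whole year's sequence (a month boundary
#' is not a data boundary). Missing days are skipped, not imputed;
#' `n_observed_days` records actual coverage and a warning is issued below
#' 90% calendar coverage.
#'
#' @param met daily meteorological `data.frame` (may hold several cities).
#' @param air daily PM2.5 `data.frame` for the same cities.
#' @param years integer years to tabulate (default: all years present in
#'   both sources).
#' @param by `"year"` for annual rows, `"month"` for monthly sub-counts.
#' @param wind_threshold,wet_threshold,rh_lo,rh_hi,pm25_threshold,require_aqi
#'   thresholds passed to the individual counters.
#' @return a `data.frame` with columns `city`, `year` (and `month` when
#'   `by = "month"`), `ws_days`, `npd_days`, `ptc_days`, `npc_days`,
#'   `rh_days`, `pm25_pollution_days`, `n_observed_days`.
#' @export
build_disaster_panel <- function(met, air, years = NULL, by = c("year", "month"),
                                 wind_threshold = 1.5, wet_threshold = 0,
                                 rh_lo = 60, rh_hi = 90,
                                 pm25_threshold = 75, require_aqi = FALSE) {
  by <- match.arg(by)
  met <- validate_met(met)
  air <- validate_air(air)
  cities <- sort(unique(met$city))
  if (!setequal(cities, unique(air$city))) {
    stop_hazedea("meteorological and air series cover different cities",
                 "validation")
  }
  met_years <- as.integer(format(met$date, "%Y"))
  air_years <- as.integer(format(air$date, "%Y"))
  if (is.null(years)) years <- sort(intersect(unique(met_years), unique(air_years)))
  rows <- list()
  for (ct in cities) {
    for (yr in years) {
      m <- met[met$city == ct, , drop = FALSE]
      m <- m[as.integer(format(m$date, "%Y")) == yr, , drop = FALSE]
      a <- air[air$city == ct, , drop = FALSE]
      a <- a[as.integer(format(a$date, "%Y")) == yr, , drop = FALSE]
      if (nrow(m) == 0L || nrow(a) == 0L) {
        stop_hazedea(sprintf("no records for city %s in year %d", ct, yr),
                     "empty_series")
      }
      m <- m[order(m$date), , drop = FALSE]
      a <- a[order(a$date), , drop = FALSE]
      cal <- if (yr %% 4 == 0 && (yr %% 100 != 0 || yr %% 400 == 0)) 366L else 365L
      if (nrow(m) < 0.9 * cal) {
        warning(sprintf("city %s year %d: only %d of %d days observed",
                        ct, yr, nrow(m), cal))
      }
      # change indicators over the within-year sequence (first day contributes
      # nothing)
      dtemp <- c(NA, diff(m$temperature))
      dpres <- c(NA, diff(m$pressure))
      ws  <- m$wind_speed < wind_threshold
      npd <- m$precipitation <= wet_threshold
      ptc <- !is.na(dtemp) & dtemp > 0
      npc <- !is.na(dpres) & dpres < 0
      rh  <- m$rh >= rh_lo & m$rh <= rh_hi & m$precipitation <= wet_threshold
      pmh <- a$pm25 > pm25_threshold
      if (require_aqi && !is.null(a$aqi_category)) {
        lvls <- c("excellent", "good", "lightly_polluted", "moderately_polluted",
                  "heavily_polluted", "severely_polluted")
        pmh <- pmh & match(a$aqi_category, lvls) >= 3L
      }
      if (by == "year") {
        rows[[length(rows) + 1L]] <- data.frame(
          city = ct, year = yr,
          ws_days = sum(ws), npd_days = sum(npd), ptc_days = sum(ptc),
          npc_days = sum(npc), rh_days = sum(rh),
          pm25_pollution_days = sum(pmh),
          n_observed_days = nrow(m), stringsAsFactors = FALSE)
      } else {
        mm <- as.integer(format(m$date, "%m"))
        am <- as.integer(format(a$date, "%m"))
        for (mo in sort(unique(mm))) {
          i <- mm == mo
          j <- am == mo
          rows[[length(rows) + 1L]] <- data.frame(
            city = ct, year = yr, month = mo,
            ws_days = sum(ws[i]), npd_days = sum(npd[i]), ptc_days = sum(ptc[i]),
            npc_days = sum(npc[i]), rh_days = sum(rh[i]),
            pm25_pollution_days = sum(pmh[j]),
            n_observed_days = sum(i), stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
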