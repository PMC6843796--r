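# Seeded synthetic generators for every input the pipeline consumes: daily
# weather, PM2.5 coupled to the disaster-point conditions, human-activity
# yearbook tables, and DEA panels (random, or with a planted efficient
# frontier and a planted influential variable). All generators are pure
# functions of (config, seed); sub-series use the documented seed-splitting
# rule in sub_seed().

#' Default weather-generator parameters
#'
#' Temperature and pressure follow AR(1) processes; wind speed is Weibull;
#' precipitation is a Bernoulli occurrence with gamma amounts on wet days;
#' relative humidity is Gaussian around a wet-day or dry-day level, clamped
#' to [0, 100]. The defaults put the five disaster-point counters in
#' plausible annual ranges for a humid subtropical climate (roughly 60-240
#' days each) - documentation values, not claims about any real station.
#'
#' @return nested list of parameters.
#' @export
default_weather_params <- function() {
  list(temperature = list(mean = 15, phi = 0.8, sd = 2),
       pressure = list(mean = 1015, phi = 0.7, sd = 3),
       wind = list(shape = 2, scale = 3),
       precip = list(p_wet = 0.45, shape = 0.7, scale = 8),
       rh = list(wet_mean = 85, dry_mean = 65, sd = 10))
}

check_weather_params <- function(p) {
  ok <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  with(p, {
    if (!ok(temperature$phi) || temperature$phi < 0 || temperature$phi >= 1 ||
        !ok(pressure$phi) || pressure$phi < 0 || pressure$phi >= 1) {
      stop_hazedea("AR(1) persistence must lie in [0, 1)", "config")
    }
    if (temperature$sd < 0 || pressure$sd < 0 || rh$sd < 0) {
      stop_hazedea("innovation SDs must be non-negative", "config")
    }
    if (precip$p_wet < 0 || precip$p_wet > 1) {
      stop_hazedea("wet-day probability must lie in [0, 1]", "config")
    }
    if (wind$shape <= 0 || wind$scale <= 0 || precip$shape <= 0 || precip$scale <= 0) {
      stop_hazedea("Weibull/gamma parameters must be positive", "config")
    }
  })
  invisible(p)
}

ar1_series <- function(n, mean, phi, sd) {
  e <- stats::rnorm(n, 0, sd)
  x <- numeric(n)
  x[1] <- mean + if (phi < 1 && sd > 0) e[1] / sqrt(1 - phi^2) else e[1]
  for (t in seq_len(n)[-1]) x[t] <- mean + phi * (x[t - 1] - mean) + e[t]
  x
}

#' Generate a daily meteorological series
#'
#' @param n_days number of days.
#' @param seed integer seed; the series is a pure function of it.
#' @param city city label.
#' @param start first calendar day.
#' @param params parameter list as in [default_weather_params()]; partial
#'   lists are merged over the defaults.
#' @return a daily meteorological `data.frame` in the layout
#'   [read_met_csv()] produces.
#' @export
gen_daily_met <- function(n_days = 365, seed = 1L, city = "C01",
                          start = as.Date("2013-01-01"),
                          params = default_weather_params()) {
  if (n_days < 1) stop_hazedea("n_days must be positive", "config")
  p <- utils::modifyList(default_weather_params(), params)
  check_weather_params(p)
  temp <- with_local_seed(sub_seed(seed, 1L),
                          ar1_series(n_days, p$temperature$mean, p$temperature$phi,
                                     p$temperature$sd))
  pres <- with_local_seed(sub_seed(seed, 2L),
                          ar1_series(n_days, p$pressure$mean, p$pressure$phi,
                                     p$pressure$sd))
  wind <- with_local_seed(sub_seed(seed, 3L),
                          stats::rweibull(n_days, p$wind$shape, p$wind$scale))
  wet <- with_local_seed(sub_seed(seed, 4L),
                         stats::runif(n_days) < p$precip$p_wet)
  amt <- with_local_seed(sub_seed(seed, 5L),
                         stats::rgamma(n_days, p$precip$shape, scale = p$precip$scale))
  precip <- ifelse(wet, amt, 0)
  rh_mean <- ifelse(wet, p$rh$wet_mean, p$rh$dry_mean)
  rh <- with_local_seed(sub_seed(seed, 6L),
                        stats::rnorm(n_days, rh_mean, p$rh$sd))
  rh <- pmin(pmax(rh, 0), 100)
  data.frame(date = seq(as.Date(start), by = "day", length.out = n_days),
             city = city, wind_speed = wind, precipitation = precip,
             temperature = temp, pressure = pres, rh = rh,
             stringsAsFactors = FALSE)
}

# Daily disaster-point indicator matrix for a single-city met series.
disaster_indicators <- function(met) {
  met <- met[order(met$date), , drop = FALSE]
  dtemp <- c(NA, diff(met$temperature))
  dpres <- c(NA, diff(met$pressure))
  cbind(ws = met$wind_speed < 1.5,
        npd = met$precipitation <= 0,
        ptc = !is.na(dtemp) & dtemp > 0,
        npc = !is.na(dpres) & dpres < 0,
        rh = met$rh >= 60 & met$rh <= 90 & met$precipitation <= 0)
}

#' Generate a daily PM2.5 series coupled to disaster-point conditions
#'
#' The probability that a day exceeds the 75 ug/m3 pollution threshold is
#' `plogis(qlogis(base_rate) + sum(coupling * indicator))` over the five
#' daily disaster-point indicators, so exceedances become more likely the
#' more of the five conditions are active; with all couplings zero the
#' exceedance rate is exactly `base_rate`. Concentrations are then drawn
#' above or below the threshold (gamma excess above, scaled beta below), and
#' an `aqi_category` column is derived from the PM2.5 sub-index bands.
#'
#' @param met single-city daily meteorological `data.frame`.
#' @param coupling numeric length-5 log-odds increments for the five
#'   indicators (ws, npd, ptc, npc, rh).
#' @param base_rate exceedance probability when no condition is active.
#' @param excess_scale scale (ug/m3) of the gamma excess above 75 on
#'   pollution days.
#' @param seed integer seed.
#' @return a daily PM2.5 `data.frame` in the layout [read_air_csv()]
#'   produces.
#' @export
gen_pm25 <- function(met, coupling = c(0.6, 0.5, 0.3, 0.3, 0.5),
                     base_rate = 0.12, excess_scale = 35, seed = 1L) {
  stopifnot(length(coupling) == 5)
  if (base_rate <= 0 || base_rate >= 1) stop_hazedea("base_rate must lie in (0,1)", "config")
  ind <- disaster_indicators(met)
  eta <- stats::qlogis(base_rate) + drop(ind %*% coupling)
  p <- stats::plogis(eta)
  n <- nrow(met)
  exceed <- with_local_seed(sub_seed(seed, 11L), stats::runif(n) < p)
  hi <- with_local_seed(sub_seed(seed, 12L),
                        75 + stats::rgamma(n, shape = 1.3, scale = excess_scale))
  lo <- with_local_seed(sub_seed(seed, 13L), 75 * stats::rbeta(n, 2, 1.5))
  pm25 <- ifelse(exceed, hi, lo)
  bands <- c(35, 75, 115, 150, 250, Inf)
  lvls <- c("excellent", "good", "lightly_polluted", "moderately_polluted",
            "heavily_polluted", "severely_polluted")
  cat_idx <- findInterval(pm25, bands, left.open = TRUE) + 1L
  data.frame(date = met$date, city = met$city, pm25 = pm25,
             aqi_category = lvls[cat_idx], stringsAsFactors = FALSE)
}

#' Generate an annual human-activity indicator table
#'
#' Draws per-city base levels for the 9 yearbook indicators on plausible
#' magnitudes (output value in hundred-million yuan, urbanization rate %,
#' population density, construction area, vehicles, bus fleet, energy
#' intensity, coal consumption, green coverage %) and applies smooth yearly
#' growth or drift, so multi-year windows have usable dispersion.
#'
#' @param cities character vector of city names.
#' @param years integer years.
#' @param seed integer seed.
#' @param growth mean annual growth rate of the scale indicators.
#' @return a `data.frame` with columns `city`, `year` and the 9 indicators.
#' @export
gen_activity_table <- function(cities, years, seed = 1L, growth = 0.07) {
  rows <- list()
  for (ci in seq_along(cities)) {
    base <- with_local_seed(sub_seed(seed, 20L + ci), {
      list(GOVIE = stats::rlnorm(1, log(6000), 0.5),
           UR = stats::runif(1, 55, 80),
           PD = stats::runif(1, 500, 4000),
           BCA = stats::rlnorm(1, log(8000), 0.5),
           CCO = stats::runif(1, 60, 300),
           NPTVO = stats::runif(1, 1500, 9000),
           EC = stats::runif(1, 0.5, 1.5),
           TCC = stats::rlnorm(1, log(1.5e7), 0.6),
           GCRBA = stats::runif(1, 38, 45))
    })
    g <- with_local_seed(sub_seed(seed, 50L + ci),
                         stats::rnorm(length(years), growth, 0.02))
    for (yi in seq_along(years)) {
      f <- prod(1 + g[seq_len(yi - 1)])
      rows[[length(rows) + 1L]] <- data.frame(
        city = cities[ci], year = years[yi],
        GOVIE = base$GOVIE * f,
        UR = min(base$UR + 0.8 * (yi - 1), 95),
        PD = base$PD * (1 + 0.01 * (yi - 1)),
        BCA = base$BCA * f,
        CCO = base$CCO * (1 + 0.1 * (yi - 1)),
        NPTVO = base$NPTVO * (1 + 0.04 * (yi - 1)),
        EC = base$EC * (1 - 0.03 * (yi - 1)),
        TCC = base$TCC * (1 + 0.02 * (yi - 1)),
        GCRBA = min(base$GCRBA + 0.3 * (yi - 1), 60),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a random indicator panel
#'
#' Unstructured stochastic DEA instances: each input column gets a scale
#' (log-uniform across columns), cell means vary around it, the output mean
#' plays the role of annual pollution days, and every SD is a cell-specific
#' coefficient of variation times the mean.
#'
#' @param n_dmus,m_inputs,s_outputs panel dimensions.
#' @param seed integer seed.
#' @param cv_range range of the per-cell coefficient of variation.
#' @return an [indicator_panel()]. With `m_inputs = 14` the standard input
#'   names and group tags are used.
#' @export
gen_random_panel <- function(n_dmus = 13, m_inputs = 14, s_outputs = 1,
                             seed = 1L, cv_range = c(0.02, 0.15)) {
  with_local_seed(sub_seed(seed, 7L), {
    n <- n_dmus; m <- m_inputs; s <- s_outputs
    scales <- 10^stats::runif(m, 0, 3)
    im <- sapply(seq_len(m), function(i) scales[i] * stats::runif(n, 0.5, 1.5))
    im <- matrix(im, n, m)
    om <- matrix(stats::runif(n * s, 30, 90), n, s)
    icv <- matrix(stats::runif(n * m, cv_range[1], cv_range[2]), n, m)
    ocv <- matrix(stats::runif(n * s, cv_range[1], cv_range[2]), n, s)
    std <- standard_input_groups()
    if (m == length(std)) {
      colnames(im) <- names(std)
      groups <- std
    } else {
      colnames(im) <- paste0("X", seq_len(m))
      groups <- stats::setNames(rep(names(table(std)), length.out = m), colnames(im))
    }
    colnames(om) <- if (s == 1) "PM25_days" else paste0("Y", seq_len(s))
    ids <- if (n == 13) jiangsu_cities() else sprintf("D%02d", seq_len(n))
    indicator_panel(ids, im, icv * im, om, ocv * om, input_groups = groups,
                    meta = list(generator = "gen_random_panel", seed = seed))
  })
}

#' Generate a DEA instance with a planted frontier and influential variable
#'
#' One designated input column discriminates between DMUs; all other input
#' columns are constant across DMUs (they bind identically under the
#' convexity constraint and so carry no frontier information). The first
#' `n_efficient` DMUs sit on a strictly concave increasing frontier in the
#' (discriminating input, output) plane and are BCC-efficient at zero noise;
#' the rest lie strictly below the frontier hull. When an influencer is
#' planted, the planted DMU is the frontier member with the strictly
#' smallest discriminating-input value and a non-maximal output: it is
#' efficient only because of that variable, so deleting the variable drops
#' its efficiency while deleting any constant column changes nothing.
#'
#' @param n_dmus,m_inputs panel dimensions (single output).
#' @param n_efficient number of planted frontier DMUs (>= 1; >= 2 when an
#'   influencer is planted).
#' @param noise_cv coefficient of variation applied to every cell SD
#'   (0 gives the deterministic instance).
#' @param planted_influencer `NULL`, or a list with integer positions `dmu`
#'   and `input` where the planted (city, variable) pair should land.
#' @param seed integer seed.
#' @return an [indicator_panel()]; `meta$planted` records the planted
#'   frontier members and, if any, the influencer pair.
#' @export
gen_dea_instance <- function(n_dmus = 6, m_inputs = 4, n_efficient = 2,
                             noise_cv = 0.05, planted_influencer = NULL,
                             seed = 1L) {
  n <- n_dmus; m <- m_inputs; E <- n_efficient
  if (E < 1 || E > n) stop_hazedea("n_efficient must lie in [1, n_dmus]", "config")
  if (noise_cv < 0) stop_hazedea("noise_cv must be non-negative", "config")
  if (!is.null(planted_influencer)) {
    if (E < 2 || m < 2) {
      stop_hazedea("planting an influencer needs n_efficient >= 2 and m_inputs >= 2",
                   "config")
    }
  }
  with_local_seed(sub_seed(seed, 8L), {
    xk <- 60 + 30 * (seq_len(E) - 1)
    yf <- 30 + 8 * sqrt(xk)          # strictly concave increasing frontier
    hull <- stats::approxfun(xk, yf, rule = 2)   # flat beyond the last point
    nd <- n - E
    xd <- yd <- numeric(0)
    if (nd > 0) {
      xd <- stats::runif(nd, min(xk) + 5, max(xk) + 40)
      yd <- hull(xd) * stats::runif(nd, 0.55, 0.85)
    }
    xcol <- c(xk, xd)
    ycol <- c(yf, yd)
    im <- matrix(rep(10^stats::runif(m, 1, 3), each = n), n, m)
    im[, 1] <- xcol
    om <- matrix(ycol, n, 1)
    ids <- sprintf("D%02d", seq_len(n))
    # move the planted pair to the requested row/column positions
    prow <- 1L; pcol <- 1L
    if (!is.null(planted_influencer)) {
      prow <- as.integer(planted_influencer$dmu %||% 1L)
      pcol <- as.integer(planted_influencer$input %||% 1L)
      stopifnot(prow >= 1, prow <= n, pcol >= 1, pcol <= m)
    }
    rperm <- seq_len(n); rperm[c(1L, prow)] <- rperm[c(prow, 1L)]
    cperm <- seq_len(m); cperm[c(1L, pcol)] <- cperm[c(pcol, 1L)]
    im <- im[order(rperm), , drop = FALSE][, order(cperm), drop = FALSE]
    om <- om[order(rperm), , drop = FALSE]
    colnames(im) <- paste0("V", seq_len(m))
    colnames(om) <- "Y"
    panel <- indicator_panel(
      ids, im, noise_cv * im, om, noise_cv * om,
      input_groups = stats::setNames(colnames(im), colnames(im)),
      meta = list(generator = "gen_dea_instance", seed = seed,
                  planted = list(
                    efficient = ids[order(rperm)[seq_len(E)]],
                    influencer = if (!is.null(planted_influencer)) {
                      list(dmu = ids[prow], input = paste0("V", pcol))
                    })))
    panel
  })
}
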