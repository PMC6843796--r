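# Independent oracles and small fixture builders used across test files.

# Brute-force day-count oracles: one-line predicate filters over the raw
# vectors, written without reference to the package counters.
oracle_counts <- function(met, air) {
  met <- met[order(met$date), ]
  air <- air[order(air$date), ]
  dry <- met$precipitation == 0
  list(ws = length(which(met$wind_speed < 1.5)),
       npd = length(which(dry)),
       ptc = length(which(met$temperature[-1] - met$temperature[-nrow(met)] > 0)),
       npc = length(which(met$pressure[-1] - met$pressure[-nrow(met)] < 0)),
       rh = length(which(met$rh >= 60 & met$rh <= 90 & dry)),
       pm = length(which(air$pm25 > 75)))
}

# Tiny hand-made meteorological frame (single city, consecutive days).
toy_met <- function(wind = c(1.0, 2.0, 1.4, 1.5, 0.9),
                    precip = c(0, 0, 1.2, 0, 0),
                    temp = c(10, 11, 10.5, 12, 12),
                    pres = c(1010, 1008, 1008, 1011, 1011),
                    rh = c(55, 65, 90, 95, 70),
                    city = "T", start = "2013-01-01") {
  n <- length(wind)
  data.frame(date = seq(as.Date(start), by = "day", length.out = n),
             city = city, wind_speed = wind, precipitation = precip,
             temperature = temp, pressure = pres, rh = rh,
             stringsAsFactors = FALSE)
}

toy_air <- function(pm25 = c(80, 75, 74.9, 100, 76), city = "T",
                    start = "2013-01-01") {
  data.frame(date = seq(as.Date(start), by = "day", length.out = length(pm25)),
             city = city, pm25 = pm25, stringsAsFactors = FALSE)
}

# Hand-built two-DMU, one-input, one-output deterministic panel.
toy_bcc_panel <- function() {
  indicator_panel(c("A", "B"),
                  input_mean = matrix(c(1, 1), 2, 1,
                                      dimnames = list(NULL, "X1")),
                  input_sd = matrix(0, 2, 1),
                  output_mean = matrix(c(2, 1), 2, 1,
                                       dimnames = list(NULL, "Y")),
                  output_sd = matrix(0, 2, 1))
}

# Exact feasibility check of a solved result against the printed model, done
# from scratch (not via package internals): relative violation of every
# constraint family.
check_certificate <- function(panel, res) {
  o <- res$o
  z <- qnorm(res$alpha)
  if (is.na(z)) z <- 0
  lam <- unname(res$lambda)
  th <- res$theta
  X <- panel$input_mean; SX <- panel$input_sd
  Y <- panel$output_mean; SY <- panel$output_sd
  viol <- abs(sum(lam) - 1)
  for (i in seq_len(ncol(X))) {
    v <- sum(lam^2 * SX[, i]^2) - lam[o]^2 * SX[o, i]^2 + (lam[o] - 1)^2 * SX[o, i]^2
    lhs <- sum(lam * X[, i]) - z * sqrt(v)
    viol <- max(viol, (lhs - X[o, i]) / max(abs(X[o, i]), 1))
  }
  for (r in seq_len(ncol(Y))) {
    w <- sum(lam^2 * SY[, r]^2) - lam[o]^2 * SY[o, r]^2 + (lam[o] - th)^2 * SY[o, r]^2
    lhs <- sum(lam * Y[, r]) + z * sqrt(w)
    viol <- max(viol, (th * Y[o, r] - lhs) / max(abs(Y[o, r]), 1))
  }
  viol
}
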