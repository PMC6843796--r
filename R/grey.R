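# Grey relational analysis (Deng's formulation): a similarity grade between
# a reference series (PM2.5 pollution days) and a comparison series (one
# disaster-point counter), used as a screening step for the input system.

#' Grey relational grade between two series
#'
#' After optional normalization, computes pointwise coefficients
#' `xi(k) = (D_min + rho * D_max) / (D(k) + rho * D_max)` with
#' `D(k) = |ref(k) - cmp(k)|` and `D_min`/`D_max` the global extrema, and
#' returns their mean. Identical (normalized) series give grade 1.
#'
#' @param reference numeric reference series (length >= 2).
#' @param comparison numeric comparison series, same length.
#' @param rho distinguishing coefficient in (0, 1], default 0.5.
#' @param normalize `"initial"` (divide each series by its first value, the
#'   default), `"mean"` (divide by its mean) or `"none"`.
#' @return the grey relational grade, a number in (0, 1].
#' @export
grey_relational_grade <- function(reference, comparison, rho = 0.5,
                                  normalize = c("initial", "mean", "none")) {
  normalize <- match.arg(normalize)
  if (length(reference) != length(comparison)) {
    stop_hazedea("series lengths differ", "validation")
  }
  if (length(reference) < 2L) stop_hazedea("series must have length >= 2", "validation")
  if (!is.numeric(rho) || rho <= 0 || rho > 1) {
    stop_hazedea("rho must lie in (0, 1]", "config")
  }
  norm1 <- function(x, what) {
    d <- switch(normalize,
                initial = x[1],
                mean = mean(x),
                none = 1)
    if (normalize != "none" && (!is.finite(d) || d == 0)) {
      stop_hazedea(sprintf("%s series cannot be %s-normalized (divisor 0)",
                           what, normalize), "degenerate")
    }
    x / d
  }
  r <- norm1(as.numeric(reference), "reference")
  cm <- norm1(as.numeric(comparison), "comparison")
  D <- abs(r - cm)
  dmax <- max(D); dmin <- min(D)
  if (dmax == 0) return(1)
  xi <- (dmin + rho * dmax) / (D + rho * dmax)
  mean(xi)
}

#' Grey relational grades of every disaster-point series vs pollution days
#'
#' Applies [grey_relational_grade()] with the pollution-day series as the
#' reference and each disaster counter as comparison. The series axis is
#' either the cities of one year or the years of one city, depending on how
#' `panel` is filtered; rows of `panel` define the observations.
#'
#' @param panel disaster panel from [build_disaster_panel()] (annual rows).
#' @param rho,normalize passed to [grey_relational_grade()].
#' @return a `data.frame` with columns `variable` and `grade`, sorted by
#'   decreasing grade.
#' @export
grey_relational_table <- function(panel, rho = 0.5,
                                  normalize = c("initial", "mean", "none")) {
  normalize <- match.arg(normalize)
  vars <- c(WS = "ws_days", NPD = "npd_days", PTC = "ptc_days",
            NPC = "npc_days", RH = "rh_days")
  ref <- panel$pm25_pollution_days
  grades <- vapply(vars, function(v) {
    grey_relational_grade(ref, panel[[v]], rho = rho, normalize = normalize)
  }, 0)
  out <- data.frame(variable = names(vars), grade = unname(grades),
                    stringsAsFactors = FALSE)
  out[order(-out$grade), , drop = FALSE]
}
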