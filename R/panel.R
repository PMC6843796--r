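# The DEA data block: per-DMU means and standard deviations for the input
# variables (5 meteorological disaster-point counters + 9 human-activity
# indicators in the standard layout) and the single output (PM2.5 pollution
# days). Cities are the decision-making units (DMUs).

#' Standard input variables and their group tags
#'
#' The 14-variable input system: meteorological factors MF{WS, NPD, PTC, NPC,
#' RH}, industrial development ID{GOVIE}, social progress SP{UR, PD, BCA},
#' transportation T{CCO, NPTVO}, energy utilization EU{EC, TCC} and
#' ecological protection EP{GCRBA}.
#'
#' @return named character vector mapping input name to group tag.
#' @export
standard_input_groups <- function() {
  c(WS = "MF", NPD = "MF", PTC = "MF", NPC = "MF", RH = "MF",
    GOVIE = "ID",
    UR = "SP", PD = "SP", BCA = "SP",
    CCO = "T", NPTVO = "T",
    EC = "EU", TCC = "EU",
    GCRBA = "EP")
}

activity_columns <- c("GOVIE", "UR", "PD", "BCA", "CCO", "NPTVO",
                      "EC", "TCC", "GCRBA")

#' Construct an indicator panel
#'
#' The container consumed by the DEA solver: means and standard deviations of
#' every input and output, per DMU.
#'
#' @param dmu_ids character vector of n DMU labels.
#' @param input_mean,input_sd n x m numeric matrices (columns named).
#' @param output_mean,output_sd n x s numeric matrices (columns named).
#' @param input_groups named character vector assigning each input a group
#'   tag; defaults to [standard_input_groups()] when the input names match,
#'   otherwise every input forms its own group.
#' @param meta free-form list (units, the SD strategy used, provenance).
#' @return an object of class `indicator_panel`.
#' @export
indicator_panel <- function(dmu_ids, input_mean, input_sd,
                            output_mean, output_sd,
                            input_groups = NULL, meta = list()) {
  input_mean <- as.matrix(input_mean)
  input_sd <- as.matrix(input_sd)
  output_mean <- as.matrix(output_mean)
  output_sd <- as.matrix(output_sd)
  n <- length(dmu_ids)
  stopifnot(nrow(input_mean) == n, nrow(output_mean) == n,
            all(dim(input_sd) == dim(input_mean)),
            all(dim(output_sd) == dim(output_mean)))
  if (is.null(colnames(input_mean))) {
    colnames(input_mean) <- paste0("X", seq_len(ncol(input_mean)))
  }
  if (is.null(colnames(output_mean))) {
    colnames(output_mean) <- paste0("Y", seq_len(ncol(output_mean)))
  }
  colnames(input_sd) <- colnames(input_mean)
  colnames(output_sd) <- colnames(output_mean)
  if (is.null(input_groups)) {
    std <- standard_input_groups()
    input_groups <- if (all(colnames(input_mean) %in% names(std))) {
      std[colnames(input_mean)]
    } else {
      stats::setNames(colnames(input_mean), colnames(input_mean))
    }
  }
  input_groups <- input_groups[colnames(input_mean)]
  if (anyNA(input_groups)) stop_hazedea("every input needs a group tag", "config")
  if (any(input_sd < 0) || any(output_sd < 0)) {
    stop_hazedea("standard deviations must be non-negative", "validation")
  }
  if (anyDuplicated(dmu_ids)) stop_hazedea("duplicate DMU ids", "validation")
  rownames(input_mean) <- rownames(input_sd) <- dmu_ids
  rownames(output_mean) <- rownames(output_sd) <- dmu_ids
  structure(list(dmu_ids = as.character(dmu_ids),
                 input_names = colnames(input_mean),
                 output_names = colnames(output_mean),
                 input_groups = input_groups,
                 input_mean = input_mean, input_sd = input_sd,
                 output_mean = output_mean, output_sd = output_sd,
                 meta = meta),
            class = "indicator_panel")
}

#' @export
print.indicator_panel <- function(x, ...) {
  cat(sprintf("<indicator_panel> %d DMUs, %d inputs (%s), %d output(s)\n",
              length(x$dmu_ids), length(x$input_names),
              paste(unique(x$input_groups), collapse = "/"),
              length(x$output_names)))
  cat("  DMUs:", paste(utils::head(x$dmu_ids, 6), collapse = ", "),
      if (length(x$dmu_ids) > 6) "...", "\n")
  invisible(x)
}

#' Mean and sample standard deviation of a variable
#'
#' Sample SD uses the n-1 denominator. A single observation yields SD 0 with
#' a warning (no dispersion information).
#'
#' @param values numeric vector, non-empty.
#' @return list with elements `mean` and `sd`.
#' @export
summarize_variable <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || all(is.na(values))) {
    stop_hazedea("no values to summarize", "empty_series")
  }
  values <- values[!is.na(values)]
  if (length(values) == 1L) {
    warning("single observation: standard deviation set to 0")
    return(list(mean = values, sd = 0))
  }
  list(mean = mean(values), sd = stats::sd(values))
}

#' Assemble the indicator panel for one evaluation year
#'
#' Combines disaster-point day counts with the 9 human-activity indicators
#' into the n x 14 input block and n x 1 output block the stochastic DEA
#' model consumes. Because the model needs a standard deviation for every
#' cell while the study evaluates one year at a time, three SD strategies are
#' supported:
#' \describe{
#'   \item{`"monthly"`}{(default) disaster counters are tallied per month
#'     within the year; the annual mean is 12 x the monthly mean and the SD
#'     is sqrt(12) x the monthly SD (months treated as independent). Annual
#'     yearbook indicators carry no sub-annual information, so their SD
#'     defaults to `activity_cv` times the mean.}
#'   \item{`"across-years"`}{each cell's mean and SD are computed over the
#'     years present in the sources (a multi-year window).}
#'   \item{`"zero-sd"`}{all SDs are 0: the deterministic DEA mode.}
#' }
#'
#' @param disaster disaster panel from [build_disaster_panel()]; must carry a
#'   `month` column for the `"monthly"` strategy, annual rows otherwise.
#' @param activity `data.frame` with columns `city`, `year` and the 9
#'   indicators `GOVIE, UR, PD, BCA, CCO, NPTVO, EC, TCC, GCRBA`.
#' @param year evaluation year (ignored by `"across-years"`, which pools all
#'   years present).
#' @param sd_strategy one of `"monthly"`, `"across-years"`, `"zero-sd"`.
#' @param activity_cv coefficient of variation assigned to annual activity
#'   indicators under the `"monthly"` strategy (default 0.05).
#' @return an [indicator_panel()].
#' @export
build_indicator_panel <- function(disaster, activity, year = NULL,
                                  sd_strategy = c("monthly", "across-years", "zero-sd"),
                                  activity_cv = 0.05) {
  sd_strategy <- match.arg(sd_strategy)
  dis_vars <- c(WS = "ws_days", NPD = "npd_days", PTC = "ptc_days",
                NPC = "npc_days", RH = "rh_days")
  out_var <- c(PM25_days = "pm25_pollution_days")
  cities <- sort(unique(disaster$city))
  problems <- character()
  if (!setequal(cities, unique(activity$city))) {
    problems <- c(problems, "disaster and activity tables cover different cities")
  }
  missing_act <- setdiff(activity_columns, names(activity))
  if (length(missing_act)) {
    problems <- c(problems, paste("missing activity columns:",
                                  paste(missing_act, collapse = ", ")))
  }
  if (sd_strategy == "monthly" && is.null(disaster$month)) {
    problems <- c(problems, "monthly strategy needs a disaster panel built with by = \"month\"")
  }
  if (sd_strategy != "across-years" && is.null(year)) {
    problems <- c(problems, "year must be given except for across-years")
  }
  if (length(problems)) stop_hazedea(paste(problems, collapse = "; "), "build_panel")

  n <- length(cities)
  m_names <- c(names(dis_vars), activity_columns)
  im <- matrix(NA_real_, n, length(m_names), dimnames = list(cities, m_names))
  isd <- im
  om <- matrix(NA_real_, n, 1, dimnames = list(cities, names(out_var)))
  osd <- om

  cell <- function(values, kind) {
    # kind: "monthly" cells scale monthly moments to annual totals
    if (kind == "monthly") {
      s <- summarize_variable(values)
      list(mean = 12 * s$mean, sd = sqrt(12) * s$sd)
    } else {
      summarize_variable(values)
    }
  }

  for (ct in cities) {
    d <- disaster[disaster$city == ct, , drop = FALSE]
    a <- activity[activity$city == ct, , drop = FALSE]
    if (sd_strategy == "monthly") {
      d <- d[d$year == year, , drop = FALSE]
      if (nrow(d) < 2L) {
        problems <- c(problems, sprintf("city %s: fewer than 2 months in %s", ct, year))
        next
      }
      for (v in seq_along(dis_vars)) {
        s <- cell(d[[dis_vars[v]]], "monthly")
        im[ct, v] <- s$mean; isd[ct, v] <- s$sd
      }
      s <- cell(d[[out_var]], "monthly")
      om[ct, 1] <- s$mean; osd[ct, 1] <- s$sd
      ay <- a[a$year == year, , drop = FALSE]
      if (nrow(ay) != 1L) {
        problems <- c(problems, sprintf("city %s: no activity row for %s", ct, year))
        next
      }
      for (v in activity_columns) {
        im[ct, v] <- ay[[v]]
        isd[ct, v] <- activity_cv * ay[[v]]
      }
    } else if (sd_strategy == "across-years") {
      if (!is.null(disaster$month)) {
        # collapse monthly rows to annual totals first
        d <- stats::aggregate(d[c(dis_vars, out_var)], by = list(year = d$year), FUN = sum)
      }
      if (nrow(d) < 2L) {
        problems <- c(problems, sprintf("city %s: across-years needs >= 2 years", ct))
        next
      }
      for (v in seq_along(dis_vars)) {
        s <- summarize_variable(d[[dis_vars[v]]])
        im[ct, v] <- s$mean; isd[ct, v] <- s$sd
      }
      s <- summarize_variable(d[[out_var]])
      om[ct, 1] <- s$mean; osd[ct, 1] <- s$sd
      for (v in activity_columns) {
        s <- summarize_variable(a[[v]])
        im[ct, v] <- s$mean; isd[ct, v] <- s$sd
      }
    } else { # zero-sd
      if (!is.null(disaster$month)) {
        d <- stats::aggregate(d[c(dis_vars, out_var)], by = list(year = d$year), FUN = sum)
      }
      d <- d[d$year == year, , drop = FALSE]
      ay <- a[a$year == year, , drop = FALSE]
      if (nrow(d) != 1L || nrow(ay) != 1L) {
        problems <- c(problems, sprintf("city %s: missing rows for %s", ct, year))
        next
      }
      for (v in seq_along(dis_vars)) im[ct, v] <- d[[dis_vars[v]]]
      om[ct, 1] <- d[[out_var]]
      for (v in activity_columns) im[ct, v] <- ay[[v]]
      isd[] <- 0; osd[] <- 0
    }
  }
  if (length(problems)) stop_hazedea(paste(problems, collapse = "; "), "build_panel")

  indicator_panel(cities, im, isd, om, osd,
                  input_groups = standard_input_groups()[m_names],
                  meta = list(year = year, sd_strategy = sd_strategy,
                              activity_cv = activity_cv,
                              units = c(WS = "days", NPD = "days", PTC = "days",
                                        NPC = "days", RH = "days",
                                        GOVIE = "1e8 yuan", UR = "%",
                                        PD = "people/km2", BCA = "1e4 m2",
                                        CCO = "1e4 cars", NPTVO = "standard units",
                                        EC = "tce/1e4 yuan", TCC = "tce",
                                        GCRBA = "%", PM25_days = "days")))
}

#' Resolve deletion targets to input column names
#' @keywords internal
#' @noRd
resolve_targets <- function(panel, targets) {
  nm <- character()
  for (t in targets) {
    if (t %in% panel$input_names) {
      nm <- c(nm, t)
    } else if (t %in% panel$input_groups) {
      nm <- c(nm, panel$input_names[panel$input_groups == t])
    } else {
      stop_hazedea(sprintf("unknown input variable or group: %s", t), "config")
    }
  }
  unique(nm)
}

#' Delete input variables or groups from a panel
#'
#' Deletion is column (constraint) removal: the DMU set and all other columns
#' are untouched. The single output cannot be deleted, and at least one input
#' must remain.
#'
#' @param panel an [indicator_panel()].
#' @param targets character vector of input names and/or group tags (e.g.
#'   `"MF"`, `"WS"`).
#' @return a new `indicator_panel` without the named inputs.
#' @export
delete_variables <- function(panel, targets) {
  stopifnot(inherits(panel, "indicator_panel"))
  drop <- resolve_targets(panel, targets)
  keep <- setdiff(panel$input_names, drop)
  if (length(keep) == 0L) stop_hazedea("cannot delete every input", "config")
  indicator_panel(panel$dmu_ids,
                  panel$input_mean[, keep, drop = FALSE],
                  panel$input_sd[, keep, drop = FALSE],
                  panel$output_mean, panel$output_sd,
                  input_groups = panel$input_groups[keep],
                  meta = c(panel$meta, list(deleted = drop)))
}

#' Write / read an indicator panel as plain text
#'
#' Serializes as two CSVs (`<prefix>_means.csv`, `<prefix>_sds.csv`, inputs
#' and outputs side by side with a `dmu` column) plus a JSON sidecar
#' (`<prefix>_meta.json`) holding names, groups and metadata.
#'
#' @param panel an [indicator_panel()].
#' @param prefix path prefix for the three files.
#' @return `prefix`, invisibly.
#' @export
write_indicator_panel <- function(panel, prefix) {
  means <- data.frame(dmu = panel$dmu_ids, panel$input_mean, panel$output_mean,
                      check.names = FALSE)
  sds <- data.frame(dmu = panel$dmu_ids, panel$input_sd, panel$output_sd,
                    check.names = FALSE)
  utils::write.csv(means, paste0(prefix, "_means.csv"), row.names = FALSE)
  utils::write.csv(sds, paste0(prefix, "_sds.csv"), row.names = FALSE)
  jsonlite::write_json(list(input_names = panel$input_names,
                            output_names = panel$output_names,
                            input_groups = as.list(panel$input_groups),
                            meta = panel$meta),
                       paste0(prefix, "_meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' @rdname write_indicator_panel
#' @export
read_indicator_panel <- function(prefix) {
  means <- utils::read.csv(paste0(prefix, "_means.csv"), check.names = FALSE)
  sds <- utils::read.csv(paste0(prefix, "_sds.csv"), check.names = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  inn <- meta$input_names
  onn <- meta$output_names
  indicator_panel(means$dmu,
                  as.matrix(means[inn]), as.matrix(sds[inn]),
                  as.matrix(means[onn]), as.matrix(sds[onn]),
                  input_groups = unlist(meta$input_groups),
                  meta = meta$meta)
}
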