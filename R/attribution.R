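# Influence analysis by variable deletion: re-solve the stochastic DEA model
# after removing grouped or single input variables and flag the DMUs whose
# stochastic efficiency changes. Deleting an input removes constraints, so
# the feasible region can only grow and efficiency can only stay or drop;
# a drop beyond `change_tol` marks the deleted variable as influential for
# that city at that risk level.

#' The 13 prefecture-level cities of Jiangsu Province
#' @return character vector of city names.
#' @export
jiangsu_cities <- function() {
  c("Nanjing", "Wuxi", "Xuzhou", "Changzhou", "Suzhou", "Nantong",
    "Lianyungang", "Huaian", "Yancheng", "Yangzhou", "Zhenjiang",
    "Taizhou", "Suqian")
}

#' Built-in regional groupings of the 13 Jiangsu cities
#'
#' `"subprovince"` splits 5 + 3 + 5 into Southern / Central / Northern;
#' `"coastal"` splits 3 + 10 into coastal / inland.
#'
#' @param type `"subprovince"` or `"coastal"`.
#' @return named list: region name -> character vector of cities (a
#'   partition of [jiangsu_cities()]).
#' @export
jiangsu_region_map <- function(type = c("subprovince", "coastal")) {
  type <- match.arg(type)
  if (type == "subprovince") {
    list(Southern = c("Nanjing", "Zhenjiang", "Suzhou", "Wuxi", "Changzhou"),
         Central = c("Yangzhou", "Taizhou", "Nantong"),
         Northern = c("Xuzhou", "Lianyungang", "Huaian", "Yancheng", "Suqian"))
  } else {
    list(Coastal = c("Nantong", "Lianyungang", "Yancheng"),
         Inland = c("Nanjing", "Xuzhou", "Changzhou", "Suzhou", "Yangzhou",
                    "Taizhou", "Wuxi", "Zhenjiang", "Huaian", "Suqian"))
  }
}

#' Variable-deletion influence scan
#'
#' For every deletion target (the six variable groups in `"group"` mode, or
#' every single input in `"single"` mode), every DMU and every risk level:
#' re-solve the stochastic DEA model on the panel without that target and
#' compare the stochastic efficiency with the baseline. Each deleted solve is
#' warm-started from the baseline solution (feasible in the relaxed problem),
#' so the recorded `eff_deleted` never exceeds `eff_baseline` numerically.
#' Solver failures are recorded as flagged rows with status `"error"`, not
#' raised.
#'
#' @param panel an [indicator_panel()] with at least two inputs.
#' @param alphas risk levels to scan.
#' @param mode `"group"` or `"single"`.
#' @param targets optional subset of deletion targets (group tags or input
#'   names); default: all groups or all inputs of the chosen mode.
#' @param change_tol efficiency change (absolute) beyond which a DMU counts
#'   as changed; default 1e-4, matching efficiencies read to four decimals.
#' @param ... solver options passed to [solve_ccdea()].
#' @return a `data.frame` of influence records: `city`, `deleted`, `mode`,
#'   `alpha`, `eff_baseline`, `eff_deleted`, `delta`
#'   (`eff_deleted - eff_baseline`), `changed`, `status`.
#' @export
influence_scan <- function(panel, alphas = default_alpha_grid(),
                           mode = c("group", "single"), targets = NULL,
                           change_tol = 1e-4, ...) {
  stopifnot(inherits(panel, "indicator_panel"))
  mode <- match.arg(mode)
  if (length(panel$input_names) < 2L) {
    stop_hazedea("influence scan needs at least two inputs", "config")
  }
  if (is.null(targets)) {
    targets <- if (mode == "group") unique(unname(panel$input_groups)) else panel$input_names
  }
  alphas <- sort(alphas)
  n <- length(panel$dmu_ids)

  base_th <- matrix(NA_real_, n, length(alphas),
                    dimnames = list(panel$dmu_ids, as.character(alphas)))
  base_lam <- vector("list", n)
  for (o in seq_len(n)) {
    base_lam[[o]] <- vector("list", length(alphas))
    warm <- NULL
    for (k in seq_along(alphas)) {
      res <- try(solve_ccdea(panel, o, alphas[k], warm_starts = warm, ...),
                 silent = TRUE)
      if (inherits(res, "try-error")) next
      base_th[o, k] <- res$theta
      base_lam[[o]][[k]] <- unname(res$lambda)
      warm <- list(unname(res$lambda))
    }
  }

  rows <- list()
  for (tg in targets) {
    dp <- delete_variables(panel, tg)
    for (o in seq_len(n)) {
      warm <- NULL
      for (k in seq_along(alphas)) {
        ws <- c(warm, base_lam[[o]][k])
        ws <- ws[!vapply(ws, is.null, TRUE)]
        res <- try(solve_ccdea(dp, o, alphas[k],
                               warm_starts = if (length(ws)) ws else NULL, ...),
                   silent = TRUE)
        eb <- 1 / base_th[o, k]
        if (inherits(res, "try-error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            city = panel$dmu_ids[o], deleted = tg, mode = mode,
            alpha = alphas[k], eff_baseline = eb, eff_deleted = NA_real_,
            delta = NA_real_, changed = NA, status = "error",
            stringsAsFactors = FALSE)
          next
        }
        warm <- list(unname(res$lambda))
        delta <- res$efficiency - eb
        rows[[length(rows) + 1L]] <- data.frame(
          city = panel$dmu_ids[o], deleted = tg, mode = mode,
          alpha = alphas[k], eff_baseline = eb, eff_deleted = res$efficiency,
          delta = delta, changed = is.finite(delta) && abs(delta) > change_tol,
          status = res$status, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "change_tol") <- change_tol
  out
}

#' Count cities whose efficiency changed per deletion target and risk level
#'
#' The shape behind the published per-year deletion tables: for each deleted
#' variable (or group) and each risk level, the number of cities flagged as
#' changed. Invariant to record order.
#'
#' @param records influence records from [influence_scan()].
#' @return a `data.frame` with one row per risk level and one column per
#'   deletion target (plus the `alpha` column).
#' @export
count_changed_cities <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    return(data.frame(alpha = numeric(0)))
  }
  targets <- sort(unique(records$deleted))
  alphas <- sort(unique(records$alpha))
  out <- data.frame(alpha = alphas)
  for (tg in targets) {
    out[[tg]] <- vapply(alphas, function(a) {
      r <- records[records$deleted == tg & records$alpha == a, ]
      sum(r$changed %in% TRUE)
    }, 0L)
  }
  out
}

#' Per-city influencing factors, partitioned by risk level
#'
#' For each city, lists every deletion target flagged at any risk level,
#' together with the levels at which it flagged (the shape of the published
#' per-city result analysis).
#'
#' @param records influence records from one or more [influence_scan()] runs
#'   (single and group mode records can be concatenated).
#' @return a `data.frame` with columns `city`, `deleted`, `mode`, `alphas`
#'   (comma-separated flagged levels); zero rows when nothing flagged.
#' @export
classify_factors <- function(records) {
  flagged <- records[records$changed %in% TRUE, , drop = FALSE]
  if (nrow(flagged) == 0L) {
    return(data.frame(city = character(0), deleted = character(0),
                      mode = character(0), alphas = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(flagged$city, flagged$deleted, flagged$mode, sep = "\r")
  rows <- lapply(split(flagged, key), function(g) {
    data.frame(city = g$city[1], deleted = g$deleted[1], mode = g$mode[1],
               alphas = paste(sort(unique(g$alpha)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$city, out$deleted), , drop = FALSE]
}

#' Regional aggregation of influence flags
#'
#' Aggregates flagged (city, alpha) pairs per region and deletion target and
#' ranks targets within each region by flag count. Regions must cover every
#' city in the records.
#'
#' @param records influence records from [influence_scan()].
#' @param region_map named list region -> character vector of cities, e.g.
#'   [jiangsu_region_map()].
#' @return a `data.frame` with columns `region`, `deleted`, `n_flags`,
#'   `rank` (1 = most flagged within the region).
#' @export
regional_summary <- function(records, region_map) {
  cities <- unique(records$city)
  mapped <- unlist(region_map, use.names = FALSE)
  missing <- setdiff(cities, mapped)
  if (length(missing)) {
    stop_hazedea(paste("cities missing from region map:",
                       paste(missing, collapse = ", ")), "config")
  }
  targets <- sort(unique(records$deleted))
  rows <- list()
  for (rg in names(region_map)) {
    rr <- records[records$city %in% region_map[[rg]], , drop = FALSE]
    nf <- vapply(targets, function(tg) {
      sum(rr$changed[rr$deleted == tg] %in% TRUE)
    }, 0L)
    rows[[rg]] <- data.frame(region = rg, deleted = targets,
                             n_flags = as.integer(nf),
                             rank = rank(-nf, ties.method = "min"),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
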