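#' Fisher-hour effort of each trip
#'
#' Effort is standardised as fisher-hours: trip duration in hours times the
#' number of people actively fishing, a unit comparable across gears and
#' boat types.
#'
#' @param trips Trip tibble (needs `duration_h`, `n_fishers`).
#' @return Numeric vector of fisher-hours, one per trip.
#' @export
trip_effort <- function(trips) {
  d <- trips$duration_h
  f <- trips$n_fishers
  if (any(is.na(d) | d <= 0) || any(is.na(f) | f < 1)) {
    abort_ssf("non-positive duration or fisher count; run QC first")
  }
  d * f
}

# per-trip catch (kg) and effort for a clean landings_data object; trips
# with no surviving landings contribute zero catch but full effort
trip_catch_effort <- function(clean) {
  stopifnot(inherits(clean, "landings_data"))
  catch <- dplyr::summarise(
    dplyr::group_by(clean$landings, .data$trip_id),
    catch_kg = sum(.data$est_weight_kg, na.rm = TRUE), .groups = "drop")
  t <- clean$trips
  t$effort_fisher_h <- trip_effort(t)
  t$catch_kg <- catch$catch_kg[match(t$trip_id, catch$trip_id)]
  t$catch_kg[is.na(t$catch_kg)] <- 0
  t$month <- year_month(t$date)
  t
}

#' Catch per unit effort by stratum
#'
#' Computes raw CPUE (kg per fisher-hour) per stratum. The default is the
#' ratio-of-totals estimator `sum(catch) / sum(effort)`, which weights trips
#' by their effort and keeps units consistent with the national raising
#' equation; a mean-of-trip-ratios variant is available for sensitivity
#' checks. Zero-catch trips contribute their effort.
#'
#' @param clean A clean `landings_data` (after [suppress_flagged()]).
#' @param by Stratifier columns, any subset of `month`, `site`,
#'   `municipality`, `boat_type`, `gear`, `habitat`.
#' @param method `"ratio"` (default) or `"mean_of_ratios"`.
#' @return Tibble with the stratifiers plus `n_trips`, `total_catch_kg`,
#'   `total_effort_fisher_h`, `cpue_kg_per_fisher_h`.
#' @export
cpue <- function(clean, by = c("month", "boat_type"),
                 method = c("ratio", "mean_of_ratios")) {
  method <- match.arg(method)
  allowed <- c("month", "site", "municipality", "boat_type", "gear", "habitat")
  if (!all(by %in% allowed)) {
    abort_ssf("unknown stratifier(s): ",
              paste(setdiff(by, allowed), collapse = ", "))
  }
  t <- trip_catch_effort(clean)
  g <- dplyr::group_by(t, dplyr::across(dplyr::all_of(by)))
  out <- dplyr::summarise(
    g,
    n_trips = dplyr::n(),
    total_catch_kg = sum(.data$catch_kg),
    total_effort_fisher_h = sum(.data$effort_fisher_h),
    cpue_kg_per_fisher_h = if (method == "ratio") {
      sum(.data$catch_kg) / sum(.data$effort_fisher_h)
    } else {
      mean(.data$catch_kg / .data$effort_fisher_h)
    },
    .groups = "drop")
  zero <- out$total_effort_fisher_h <= 0
  if (any(zero)) {
    warning(sum(zero), " stratum/strata with zero effort excluded",
            call. = FALSE)
    out <- out[!zero, ]
  }
  dplyr::arrange(out, dplyr::across(dplyr::all_of(by)))
}

#' Effort-weighted cubic smoothing spline for a CPUE series
#'
#' Fits `stats::smooth.spline` with observation weights (typically the
#' stratum's total effort, so well-sampled months anchor the curve) and
#' returns fitted values at the input times. The smoothing parameter `spar`
#' is exposed so a caller can sweep it interactively; when `NULL`,
#' generalised cross-validation picks it.
#'
#' @param time Numeric or Date vector of observation times (>= 4 distinct).
#' @param value CPUE (or any index) at each time.
#' @param weights Optional nonnegative weights, e.g. total effort.
#' @param spar Smoothing parameter in `[0, 1]`-ish range as understood by
#'   [stats::smooth.spline()]; `NULL` for automatic selection.
#' @return Tibble with `time`, `value`, `fitted`; the fitted
#'   `smooth.spline` object is attached as attribute `"spline"`.
#' @export
smooth_cpue <- function(time, value, weights = NULL, spar = NULL) {
  tnum <- as.numeric(time)
  if (length(unique(tnum)) < 4) {
    abort_ssf("need at least 4 distinct time points to smooth; ",
              "display the raw series instead")
  }
  fit <- stats::smooth.spline(tnum, value, w = weights, spar = spar,
                              cv = FALSE, keep.data = FALSE)
  fitted <- stats::predict(fit, tnum)$y
  out <- tibble::tibble(time = time, value = value, fitted = fitted)
  attr(out, "spline") <- fit
  out
}

#' Vessel activity coefficient from GPS tracks
#'
#' VAC is the average number of fishing trips per boat per month, estimated
#' per boat type from segmented vessel tracks: trips counted in the month of
#' their first ping, divided by the number of tracked boats of that type.
#' The default denominator is the month's active roster (units with at least
#' one ping that month); pass a fixed `roster` of instrumented units to
#' include boats that never left harbour (they then contribute zero trips).
#'
#' @param tracks Ping tibble from [read_tracks()] / [segment_tracks()].
#' @param roster Optional tibble (`unit_id`, `boat_type`) fixing the
#'   denominator per month.
#' @param statistic `"mean"` (default) or `"median"` of per-boat monthly
#'   trip counts.
#' @return Tibble with `month`, `boat_type`, `n_trips`, `n_boats`, `vac`.
#' @export
vac <- function(tracks, roster = NULL, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  starts <- dplyr::summarise(
    dplyr::group_by(tracks, .data$track_id),
    unit_id = dplyr::first(.data$unit_id),
    boat_type = dplyr::first(.data$boat_type),
    start = min(.data$timestamp), .groups = "drop")
  starts$month <- format(starts$start, "%Y-%m")

  per_boat <- dplyr::count(starts, .data$month, .data$boat_type,
                           .data$unit_id, name = "n_trips")
  if (!is.null(roster)) {
    # expand to the full roster each observed month, zero-filling idle boats
    months <- unique(per_boat$month)
    full <- tidyr::crossing(month = months,
                            roster[, c("unit_id", "boat_type")])
    per_boat <- dplyr::left_join(full, per_boat,
                                 by = c("month", "boat_type", "unit_id"))
    per_boat$n_trips[is.na(per_boat$n_trips)] <- 0L
  }
  out <- dplyr::summarise(
    dplyr::group_by(per_boat, .data$month, .data$boat_type),
    n_trips = sum(.data$n_trips),
    n_boats = dplyr::n_distinct(.data$unit_id),
    vac = if (statistic == "mean") sum(.data$n_trips) / dplyr::n_distinct(.data$unit_id)
          else median(.data$n_trips),
    .groups = "drop")
  dplyr::arrange(out, .data$month, .data$boat_type)
}

#' Median effort per trip
#'
#' EPT is the median trip effort in fisher-hours per boat type (the median
#' is robust to the long right tail of multi-day trips; for an even number
#' of trips it is the mean of the two middle values).
#'
#' @param trips Clean trip tibble.
#' @param by Grouping column, default `"boat_type"`.
#' @return Tibble with the grouping column and `ept_fisher_h`.
#' @export
ept <- function(trips, by = "boat_type") {
  if (nrow(trips) == 0) abort_ssf("no trips to compute EPT from")
  trips$.effort <- trip_effort(trips)
  out <- dplyr::summarise(
    dplyr::group_by(trips, dplyr::across(dplyr::all_of(by))),
    n_trips = dplyr::n(),
    ept_fisher_h = median(.data$.effort), .groups = "drop")
  dplyr::arrange(out, dplyr::across(dplyr::all_of(by)))
}

#' National monthly catch estimate
#'
#' Raises sampled landings to the whole fleet:
#' \deqn{C = \sum_b CPUE_b \times EPT_b \times VAC_b \times N_b \times 0.001}
#' where `b` indexes boat types, CPUE is kg per fisher-hour, EPT the median
#' fisher-hours per trip, VAC the average trips per boat per month, `N_b`
#' the census count of boats of type `b`, and 0.001 converts kg to tonnes.
#' Shore-based fishing is excluded from the raising (it contributes a
#' negligible share of landings and has no vessel census).
#'
#' @param cpue_tbl Tibble with `boat_type` and `cpue_kg_per_fisher_h`.
#' @param ept_tbl Tibble with `boat_type` and `ept_fisher_h`.
#' @param vac_tbl Tibble with `boat_type` and `vac`.
#' @param census Tibble with `boat_type` and `n_boats` (see [read_census()]).
#' @return A `fleet_estimate` tibble, one row per raised boat type with the
#'   four components and `catch_t`; the grand total is `sum(x$catch_t)` and
#'   is also attached as attribute `"total_t"`.
#' @export
national_catch <- function(cpue_tbl, ept_tbl, vac_tbl, census) {
  census <- validate_census(census)
  raised <- census[census$boat_type != "shore" & census$n_boats > 0, ]
  comp <- list(CPUE = cpue_tbl, EPT = ept_tbl, VAC = vac_tbl)
  for (nm in names(comp)) {
    missing <- setdiff(raised$boat_type, comp[[nm]]$boat_type)
    if (length(missing) > 0) {
      abort_ssf(nm, " missing for boat type(s) with census boats: ",
                paste(missing, collapse = ", "))
    }
  }
  out <- tibble::tibble(
    boat_type = raised$boat_type,
    cpue_kg_per_fisher_h =
      cpue_tbl$cpue_kg_per_fisher_h[match(raised$boat_type, cpue_tbl$boat_type)],
    ept_fisher_h =
      ept_tbl$ept_fisher_h[match(raised$boat_type, ept_tbl$boat_type)],
    vac = vac_tbl$vac[match(raised$boat_type, vac_tbl$boat_type)],
    n_boats = raised$n_boats
  )
  out$catch_t <- out$cpue_kg_per_fisher_h * out$ept_fisher_h * out$vac *
    out$n_boats * 0.001
  if (any(out$catch_t < 0, na.rm = TRUE)) {
    abort_ssf("negative catch estimate; check the inputs")
  }
  attr(out, "total_t") <- sum(out$catch_t)
  class(out) <- c("fleet_estimate", class(out))
  out
}

#' @export
print.fleet_estimate <- function(x, ...) {
  NextMethod()
  cat(sprintf("# total national catch: %.3f t\n", attr(x, "total_t")))
  invisible(x)
}

#' Grid-binned fishing effort heat map
#'
#' Bins GPS pings onto an equirectangular grid over the tracks' bounding
#' box. At a fixed ping cadence the count of pings in a cell is proportional
#' to vessel time spent there, so the grid is a relative effort surface.
#'
#' @param tracks Ping tibble.
#' @param cell_size_km Grid cell edge in km; default 1.
#' @param normalize If `TRUE`, also return counts rescaled to `[0, 1]`.
#' @return A list of class `effort_grid`: `counts` (matrix, rows = y from
#'   south, cols = x from west), `x_breaks_km`, `y_breaks_km`, `origin`
#'   (lat/lon of the bounding-box corner) and optionally `normalized`.
#' @export
effort_heatmap <- function(tracks, cell_size_km = 1, normalize = FALSE) {
  if (nrow(tracks) == 0) abort_ssf("no pings to bin")
  origin <- c(lat = min(tracks$lat), lon = min(tracks$lon))
  xy <- local_xy(tracks$lat, tracks$lon, origin)
  nx <- max(1L, ceiling(max(xy[, 1]) / cell_size_km))
  ny <- max(1L, ceiling(max(xy[, 2]) / cell_size_km))
  ix <- pmin(pmax(floor(xy[, 1] / cell_size_km) + 1L, 1L), nx)
  iy <- pmin(pmax(floor(xy[, 2] / cell_size_km) + 1L, 1L), ny)
  counts <- matrix(0L, nrow = ny, ncol = nx)
  tab <- table(factor(iy, levels = seq_len(ny)), factor(ix, levels = seq_len(nx)))
  counts[] <- as.integer(tab)
  out <- list(counts = counts,
              x_breaks_km = seq(0, nx) * cell_size_km,
              y_breaks_km = seq(0, ny) * cell_size_km,
              origin = origin,
              cell_size_km = cell_size_km)
  if (normalize) {
    out$normalized <- if (max(counts) > 0) counts / max(counts) else counts
  }
  structure(out, class = "effort_grid")
}

#' @export
print.effort_grid <- function(x, ...) {
  cat(sprintf("<effort_grid> %d x %d cells of %g km, %d pings\n",
              nrow(x$counts), ncol(x$counts), x$cell_size_km, sum(x$counts)))
  invisible(x)
}

#' Write an effort grid as a long-format CSV
#'
#' @param grid An `effort_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_effort_grid <- function(grid, path) {
  long <- expand.grid(y = seq_len(nrow(grid$counts)),
                      x = seq_len(ncol(grid$counts)))
  long$count <- as.vector(grid$counts)
  long <- long[long$count > 0, c("x", "y", "count")]
  long$x_km <- (long$x - 0.5) * grid$cell_size_km
  long$y_km <- (long$y - 0.5) * grid$cell_size_km
  readr::write_csv(tibble::as_tibble(long[order(long$x, long$y), ]), path,
                   progress = FALSE)
  invisible(path)
}
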