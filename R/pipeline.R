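#' Link GPS tracks to enumerated trips
#'
#' A track belongs to a trip when it comes from the same tracker unit and
#' starts on the trip's date; when a boat made several trips on one day,
#' tracks and trips are paired in time order (tracks by start time, trips by
#' trip id). Tracks with no matching trip remain unlinked — those are the
#' tracked-but-unobserved trips the classifier imputes.
#'
#' @param trips Trip tibble with a `unit_id` column.
#' @param tracks Segmented ping tibble.
#' @return Tibble `trip_id`, `track_id` with one row per linked pair.
#' @export
link_tracks <- function(trips, tracks) {
  starts <- dplyr::summarise(
    dplyr::group_by(tracks, .data$track_id),
    unit_id = dplyr::first(.data$unit_id),
    start = min(.data$timestamp), .groups = "drop")
  starts$date <- as.Date(starts$start, tz = "UTC")
  starts <- dplyr::arrange(starts, .data$unit_id, .data$start)
  starts <- dplyr::mutate(
    dplyr::group_by(starts, .data$unit_id, .data$date),
    .k = dplyr::row_number())
  starts <- dplyr::ungroup(starts)

  t <- trips[!is.na(trips$unit_id), c("trip_id", "unit_id", "date")]
  t <- dplyr::arrange(t, .data$unit_id, .data$date, .data$trip_id)
  t <- dplyr::mutate(
    dplyr::group_by(t, .data$unit_id, .data$date),
    .k = dplyr::row_number())
  t <- dplyr::ungroup(t)

  linked <- dplyr::inner_join(t, starts, by = c("unit_id", "date", ".k"))
  linked[, c("trip_id", "track_id")]
}

#' Run the daily parse: ingest, weigh, flag, suppress, link
#'
#' The batch pipeline a monitoring programme runs on each new export:
#' read the landings survey, estimate catch weights from length, apply the
#' QC filters, split clean records from the flagged report, and link vessel
#' tracks to trips. Re-running on identical inputs yields identical outputs.
#'
#' @param landings A landings CSV path or a `landings_data` object.
#' @param species A species CSV path or species tibble.
#' @param tracks Optional tracks file path or ping tibble.
#' @param matrix Gear/habitat validity matrix.
#' @param bounds [qc_bounds()] thresholds.
#' @param gap_hours Track segmentation gap (hours).
#' @param out_dir Optional directory; when given, writes `clean_store.csv`,
#'   `flagged_report.csv`, `parse_errors.csv` and `track_links.csv`.
#' @return List: `clean` (a `landings_data`), `report`, `links`,
#'   `parse_errors`, `tracks`.
#' @export
run_parse <- function(landings, species, tracks = NULL,
                      matrix = default_gear_habitat_matrix(),
                      bounds = qc_bounds(), gap_hours = 2, out_dir = NULL) {
  if (is_string(species)) species <- read_species(species)
  data <- if (is_string(landings)) read_landings(landings) else landings
  stopifnot(inherits(data, "landings_data"))
  if (!is.null(tracks) && is_string(tracks)) {
    tracks <- read_tracks(tracks, gap_hours = gap_hours)
  }

  data <- add_weights(data, species)
  data <- apply_filters(data, species, matrix = matrix, bounds = bounds)
  out <- suppress_flagged(data)
  links <- if (!is.null(tracks)) link_tracks(out$clean$trips, tracks) else
    tibble::tibble(trip_id = character(), track_id = character())

  result <- list(clean = out$clean, report = out$report, links = links,
                 parse_errors = data$parse_errors, tracks = tracks)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    clean_flat <- dplyr::left_join(
      dplyr::mutate(out$clean$landings, flags = NULL),
      out$clean$trips, by = "trip_id")
    readr::write_csv(clean_flat, file.path(out_dir, "clean_store.csv"),
                     progress = FALSE)
    readr::write_csv(out$report, file.path(out_dir, "flagged_report.csv"),
                     progress = FALSE)
    readr::write_csv(data$parse_errors,
                     file.path(out_dir, "parse_errors.csv"), progress = FALSE)
    readr::write_csv(links, file.path(out_dir, "track_links.csv"),
                     progress = FALSE)
  }
  result
}

#' Month-aggregated summary of the clean store
#'
#' @param clean A clean `landings_data`.
#' @return Tibble keyed by (month, municipality, boat_type, gear, habitat)
#'   with `n_trips`, `total_catch_kg`, `total_effort_fisher_h`,
#'   `cpue_kg_per_fisher_h`, ordered lexicographically.
#' @export
month_summary <- function(clean) {
  t <- trip_catch_effort(clean)
  out <- dplyr::summarise(
    dplyr::group_by(t, .data$month, .data$municipality, .data$boat_type,
                    .data$gear, .data$habitat),
    n_trips = dplyr::n(),
    total_catch_kg = sum(.data$catch_kg),
    total_effort_fisher_h = sum(.data$effort_fisher_h),
    cpue_kg_per_fisher_h = sum(.data$catch_kg) / sum(.data$effort_fisher_h),
    .groups = "drop")
  dplyr::arrange(out, .data$month, .data$municipality, .data$boat_type,
                 .data$gear, .data$habitat)
}

#' Species composition of the clean catch
#'
#' @param clean A clean `landings_data`.
#' @param month Optional `"YYYY-MM"` filter.
#' @return Tibble `taxon_code`, `catch_kg`, `share` (shares sum to 1).
#' @export
species_composition <- function(clean, month = NULL) {
  l <- clean$landings
  if (!is.null(month)) {
    t <- clean$trips
    keep <- t$trip_id[year_month(t$date) == month]
    l <- l[l$trip_id %in% keep, ]
  }
  out <- dplyr::summarise(dplyr::group_by(l, .data$taxon_code),
                          catch_kg = sum(.data$est_weight_kg, na.rm = TRUE),
                          .groups = "drop")
  total <- sum(out$catch_kg)
  out$share <- if (total > 0) out$catch_kg / total else 0
  dplyr::arrange(out, dplyr::desc(.data$catch_kg))
}

#' Produce the monthly analytical bundle
#'
#' Composes the reporting outputs from a clean store: the month summary,
#' CPUE tables, species composition, the national fleet estimate (when a
#' census and VAC source are available) and the effort heat map (when
#' tracks are available).
#'
#' @param clean A clean `landings_data`.
#' @param census Optional fleet census tibble.
#' @param month Optional `"YYYY-MM"`; defaults to all months present for
#'   the summary and the latest month for the fleet estimate.
#' @param tracks Optional ping tibble for VAC and the heat map.
#' @param vac_table Optional precomputed VAC tibble (used when no tracks).
#' @param cell_size_km Heat map cell size.
#' @param out_dir Optional output directory for CSVs.
#' @return List: `summary`, `cpue`, `composition`, and where inputs allow
#'   `fleet_estimate` and `heatmap`.
#' @export
run_report <- function(clean, census = NULL, month = NULL, tracks = NULL,
                       vac_table = NULL, cell_size_km = 1, out_dir = NULL) {
  months_present <- unique(year_month(clean$trips$date))
  if (!is.null(month) && !month %in% months_present) {
    warning("no clean data for month ", month, call. = FALSE)
  }
  bundle <- list(
    summary = month_summary(clean),
    cpue = cpue(clean, by = c("month", "boat_type")),
    composition = species_composition(clean, month = month)
  )

  if (!is.null(tracks) && is.null(vac_table)) vac_table <- vac(tracks)
  if (!is.null(census) && !is.null(vac_table)) {
    m <- month %||% max(months_present)
    trips_m <- clean$trips[year_month(clean$trips$date) == m, ]
    clean_m <- new_landings_data(
      trips_m, clean$landings[clean$landings$trip_id %in% trips_m$trip_id, ])
    vac_m <- if ("month" %in% names(vac_table)) {
      vac_table[vac_table$month == m, ]
    } else {
      vac_table
    }
    if (nrow(trips_m) > 0) {
      bundle$fleet_estimate <- national_catch(
        cpue(clean_m, by = "boat_type"),
        ept(trips_m),
        vac_m,
        census)
    }
  }
  if (!is.null(tracks)) {
    bundle$heatmap <- effort_heatmap(tracks, cell_size_km = cell_size_km)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_month_summary(bundle$summary,
                        file.path(out_dir, "month_summary.csv"))
    readr::write_csv(bundle$cpue, file.path(out_dir, "cpue.csv"),
                     progress = FALSE)
    readr::write_csv(bundle$composition,
                     file.path(out_dir, "species_composition.csv"),
                     progress = FALSE)
    if (!is.null(bundle$fleet_estimate)) {
      readr::write_csv(bundle$fleet_estimate,
                       file.path(out_dir, "fleet_estimate.csv"),
                       progress = FALSE)
    }
    if (!is.null(bundle$heatmap)) {
      write_effort_grid(bundle$heatmap, file.path(out_dir, "effort_grid.csv"))
    }
  }
  bundle
}
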