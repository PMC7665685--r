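#' Read vessel GPS pings and segment them into trips
#'
#' Accepts either a CSV of points (`unit_id`, `timestamp`, `lat`, `lon`,
#' optional `boat_type`) or a GeoJSON FeatureCollection of Point features
#' carrying the same fields as properties. Points are partitioned by tracker
#' unit, ordered by time, de-duplicated (a repeated timestamp within a unit
#' keeps the first point, with a warning) and screened for valid coordinate
#' ranges (out-of-range points are dropped with a warning). A time gap
#' longer than `gap_hours` between consecutive pings of a unit starts a new
#' track, which is how a continuous point stream is segmented into discrete
#' fishing trips.
#'
#' @param path CSV or GeoJSON file of GPS points.
#' @param gap_hours Gap threshold (hours) that separates two trips of the
#'   same unit; default 2.
#' @param tz Timezone used to interpret timestamps; default UTC.
#' @return A tibble of pings with columns `track_id`, `unit_id`,
#'   `boat_type`, `timestamp`, `lat`, `lon`, time-ordered within track.
#' @export
read_tracks <- function(path, gap_hours = 2, tz = "UTC") {
  ext <- tolower(tools::file_ext(path))
  pings <- if (ext %in% c("geojson", "json")) {
    read_tracks_geojson(path)
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = "c"),
                    show_col_types = FALSE, progress = FALSE)
  }
  required <- c("unit_id", "timestamp", "lat", "lon")
  missing <- setdiff(required, names(pings))
  if (length(missing) > 0) {
    abort_ssf("track file is missing column(s): ",
              paste(missing, collapse = ", "))
  }
  if (!"boat_type" %in% names(pings)) pings$boat_type <- NA_character_
  pings <- tibble::tibble(
    unit_id = as.character(pings$unit_id),
    boat_type = normalize_enum(pings$boat_type, boat_types()),
    timestamp = parse_timestamp(pings$timestamp, tz),
    lat = suppressWarnings(as.numeric(pings$lat)),
    lon = suppressWarnings(as.numeric(pings$lon))
  )
  segment_tracks(pings, gap_hours = gap_hours)
}

parse_timestamp <- function(x, tz = "UTC") {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  out <- as.POSIXct(x, tz = tz,
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  out
}

read_tracks_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) abort_ssf("GeoJSON must be a FeatureCollection")
  rows <- lapply(gj$features, function(f) {
    coords <- f$geometry$coordinates
    props <- f$properties
    tibble::tibble(
      unit_id = as.character(props$unit_id %||% NA_character_),
      boat_type = as.character(props$boat_type %||% NA_character_),
      timestamp = as.character(props$timestamp %||% NA_character_),
      lon = as.numeric(coords[[1]]),
      lat = as.numeric(coords[[2]])
    )
  })
  dplyr::bind_rows(rows)
}

#' Segment a ping stream into tracks by time gaps
#'
#' @param pings Tibble with `unit_id`, `timestamp`, `lat`, `lon` and
#'   optionally `boat_type`.
#' @inheritParams read_tracks
#' @return Tibble of pings with a `track_id` column; every output track has
#'   strictly increasing timestamps and at least 2 pings (singleton segments
#'   are dropped with a warning, since a single point cannot describe a
#'   trip).
#' @export
segment_tracks <- function(pings, gap_hours = 2) {
  pings <- tibble::as_tibble(pings)
  if (!"boat_type" %in% names(pings)) pings$boat_type <- NA_character_

  bad_coord <- is.na(pings$lat) | is.na(pings$lon) |
    abs(pings$lat) > 90 | abs(pings$lon) > 180 | is.na(pings$timestamp)
  if (any(bad_coord)) {
    warning(sum(bad_coord), " ping(s) dropped: invalid coordinates or timestamp",
            call. = FALSE)
    pings <- pings[!bad_coord, ]
  }

  pings <- dplyr::arrange(pings, .data$unit_id, .data$timestamp)
  dup <- duplicated(pings[, c("unit_id", "timestamp")])
  if (any(dup)) {
    warning(sum(dup), " duplicate timestamp(s) dropped within unit(s)",
            call. = FALSE)
    pings <- pings[!dup, ]
  }

  pings <- dplyr::group_by(pings, .data$unit_id)
  pings <- dplyr::mutate(
    pings,
    .gap = c(0, diff(as.numeric(.data$timestamp))) > gap_hours * 3600,
    .seg = cumsum(.data$.gap) + 1L,
    track_id = sprintf("%s-%03d", .data$unit_id, .data$.seg)
  )
  pings <- dplyr::ungroup(pings)
  pings$.gap <- NULL
  pings$.seg <- NULL

  sizes <- table(pings$track_id)
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons) > 0) {
    warning(length(singletons), " singleton track(s) dropped", call. = FALSE)
    pings <- pings[!pings$track_id %in% singletons, ]
  }
  pings[, c("track_id", "unit_id", "boat_type", "timestamp", "lat", "lon")]
}

#' Write pings to CSV or GeoJSON
#'
#' @param pings Ping tibble as returned by [read_tracks()] or produced by
#'   the simulator.
#' @param path Output path; a `.geojson` extension selects GeoJSON output,
#'   anything else CSV.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(pings, path) {
  ext <- tolower(tools::file_ext(path))
  out <- pings[, intersect(c("unit_id", "boat_type", "timestamp", "lat", "lon"),
                           names(pings))]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (ext == "geojson") {
    features <- lapply(seq_len(nrow(out)), function(i) {
      list(
        type = "Feature",
        geometry = list(type = "Point",
                        coordinates = c(out$lon[i], out$lat[i])),
        properties = list(unit_id = out$unit_id[i],
                          boat_type = out$boat_type[i],
                          timestamp = out$timestamp[i])
      )
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = features),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}
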