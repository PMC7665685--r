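# Flat landings CSV schema: one row per species-group landed per trip, with
# the trip-level columns repeated on every row (the shape an enumerator form
# export takes). Mandatory columns below; record_id, municipality, price,
# price_basis and unit_id are optional.
LANDINGS_MANDATORY <- c("trip_id", "site", "date", "boat_type", "gear",
                        "habitat", "n_fishers", "duration_h", "taxon_code",
                        "fork_length_cm", "n_individuals")
LANDINGS_OPTIONAL <- c("record_id", "municipality", "price", "price_basis",
                       "unit_id")

new_landings_data <- function(trips, landings, parse_errors = NULL) {
  structure(
    list(
      trips = tibble::as_tibble(trips),
      landings = tibble::as_tibble(landings),
      parse_errors = tibble::as_tibble(
        parse_errors %||%
          tibble::tibble(row = integer(), field = character(),
                         value = character(), message = character())
      )
    ),
    class = "landings_data"
  )
}

#' @export
print.landings_data <- function(x, ...) {
  n_flagged <- sum(lengths(x$landings$flags) > 0)
  cat("<landings_data>\n")
  cat("  trips:    ", nrow(x$trips), "\n")
  cat("  landings: ", nrow(x$landings), " (", n_flagged, " flagged)\n",
      sep = "")
  if (nrow(x$parse_errors) > 0) {
    cat("  parse errors:", nrow(x$parse_errors), "\n")
  }
  invisible(x)
}

#' Read a landings survey CSV into trips and landing records
#'
#' Parses a flat landings export (one row per species-group landed per trip)
#' into a `landings_data` object holding a trip table and a landing-record
#' table. Enum fields (`boat_type`, `gear`, `habitat`) are matched
#' case-insensitively against the package vocabularies. Rows that cannot be
#' parsed (malformed numbers or dates, unknown enum levels) are skipped and
#' collected in a machine-readable parse-error report rather than aborting
#' the ingest; a missing mandatory column, by contrast, is a hard error.
#' Unknown `taxon_code` values are tolerated here and flagged `FORMAT_ERROR`
#' later by [apply_filters()].
#'
#' @param path Path to the landings CSV (UTF-8, comma-separated, ISO-8601
#'   dates).
#' @param species Optional species table; when given, estimated weights are
#'   attached via [add_weights()].
#' @return A `landings_data` object with elements `trips`, `landings` and
#'   `parse_errors`.
#' @export
read_landings <- function(path, species = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(LANDINGS_MANDATORY, names(raw))
  if (length(missing) > 0) {
    abort_ssf("landings file is missing mandatory column(s): ",
              paste(missing, collapse = ", "))
  }
  out <- parse_landings(raw)
  if (!is.null(species)) out <- add_weights(out, species)
  out
}

# shared by read_landings and the in-memory constructor used in tests
parse_landings <- function(raw) {
  raw <- tibble::as_tibble(raw)
  n <- nrow(raw)
  if (!"record_id" %in% names(raw) || all(is.na(raw$record_id))) {
    raw$record_id <- sprintf("R%05d", seq_len(n))
  }
  for (col in setdiff(LANDINGS_OPTIONAL, names(raw))) {
    raw[[col]] <- NA_character_
  }

  errs <- list()
  note <- function(rows, field, value, msg) {
    if (length(rows) > 0) {
      errs[[length(errs) + 1]] <<- tibble::tibble(
        row = rows, record_id = raw$record_id[rows], field = field,
        value = as.character(value), message = msg)
    }
  }

  num <- function(field) {
    v <- suppressWarnings(as.numeric(raw[[field]]))
    bad <- which(is.na(v) & !is.na(raw[[field]]))
    note(bad, field, raw[[field]][bad], "not a number")
    v
  }
  n_fishers <- num("n_fishers")
  duration_h <- num("duration_h")
  fork_length_cm <- num("fork_length_cm")
  n_individuals <- num("n_individuals")
  price <- suppressWarnings(as.numeric(raw$price))
  bad_price <- which(is.na(price) & !is.na(raw$price) & raw$price != "")
  note(bad_price, "price", raw$price[bad_price], "not a number")

  date <- suppressWarnings(as.Date(raw$date, format = "%Y-%m-%d"))
  bad_date <- which(is.na(date) & !is.na(raw$date))
  note(bad_date, "date", raw$date[bad_date], "not an ISO-8601 date")

  enum <- function(field, vocab) {
    v <- normalize_enum(raw[[field]], vocab)
    bad <- which(is.na(v) & !is.na(raw[[field]]))
    note(bad, field, raw[[field]][bad], "unknown category")
    v
  }
  boat_type <- enum("boat_type", boat_types())
  gear <- enum("gear", gear_types())
  habitat <- enum("habitat", habitat_types())
  price_basis <- normalize_enum(raw$price_basis, c("per_kg", "per_fish"))
  price_basis[is.na(price_basis)] <- "per_kg"

  mandatory_ok <- !is.na(raw$trip_id) & !is.na(date) & !is.na(boat_type) &
    !is.na(gear) & !is.na(habitat) & !is.na(n_fishers) & !is.na(duration_h) &
    !is.na(fork_length_cm) & !is.na(n_individuals) & !is.na(raw$taxon_code)
  parse_errors <- if (length(errs) > 0) dplyr::bind_rows(errs) else NULL
  keep <- which(mandatory_ok)

  landings <- tibble::tibble(
    record_id = raw$record_id[keep],
    trip_id = raw$trip_id[keep],
    taxon_code = raw$taxon_code[keep],
    fork_length_cm = fork_length_cm[keep],
    n_individuals = n_individuals[keep],
    price = price[keep],
    price_basis = price_basis[keep],
    est_weight_kg = NA_real_,
    flags = rep(list(character()), length(keep))
  )

  trips <- tibble::tibble(
    trip_id = raw$trip_id[keep],
    site = raw$site[keep],
    municipality = raw$municipality[keep],
    date = date[keep],
    boat_type = boat_type[keep],
    gear = gear[keep],
    habitat = habitat[keep],
    n_fishers = n_fishers[keep],
    duration_h = duration_h[keep],
    unit_id = raw$unit_id[keep]
  )
  trips <- dplyr::distinct(trips, .data$trip_id, .keep_all = TRUE)

  new_landings_data(trips, landings, parse_errors)
}

#' Write a landings_data object back to the flat CSV schema
#'
#' Emits the raw survey schema (trip columns repeated per landing row) so
#' that `read_landings(write_landings(x))` round-trips all surveyed fields.
#' Derived columns (`est_weight_kg`, `flags`) are not written: they are
#' recomputed on ingest.
#'
#' @param x A `landings_data` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landings <- function(x, path) {
  stopifnot(inherits(x, "landings_data"))
  flat <- dplyr::left_join(x$landings, x$trips, by = "trip_id")
  flat <- flat[, c("record_id", "trip_id", "site", "municipality", "date",
                   "boat_type", "gear", "habitat", "n_fishers", "duration_h",
                   "unit_id", "taxon_code", "fork_length_cm", "n_individuals",
                   "price", "price_basis")]
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

#' Export a month-aggregated summary table
#'
#' One row per (year-month, municipality, boat type, gear, habitat) stratum
#' with trip counts, total catch, total fisher-hour effort and CPUE, in
#' deterministic lexicographic row order — the downloadable summary a
#' monitoring dashboard exposes.
#'
#' @param summary A summary tibble from [month_summary()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_month_summary <- function(summary, path) {
  required <- c("month", "municipality", "boat_type", "gear", "habitat",
                "n_trips", "total_catch_kg", "total_effort_fisher_h",
                "cpue_kg_per_fisher_h")
  missing <- setdiff(required, names(summary))
  if (length(missing) > 0) {
    abort_ssf("summary is missing column(s): ", paste(missing, collapse = ", "))
  }
  summary <- dplyr::arrange(summary[required], .data$month,
                            .data$municipality, .data$boat_type, .data$gear,
                            .data$habitat)
  readr::write_csv(summary, path, progress = FALSE)
  invisible(path)
}
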