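#' @importFrom rlang %||% .data
#' @importFrom stats approx median rlnorm rnorm runif rpois setNames
#' @importFrom utils head
NULL

# abort with a consistent prefix; keeps call noise out of user-facing errors
abort_ssf <- function(...) stop(..., call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# "2018-05" from a Date vector
year_month <- function(date) format(date, "%Y-%m")

# normalise free-text categorical values: case-insensitive, spaces and
# hyphens collapse to underscores ("Gill net" -> "gill_net", "FAD" -> "fad")
normalize_enum <- function(x, vocab) {
  key <- gsub("[ -]+", "_", tolower(trimws(as.character(x))))
  key[!key %in% vocab] <- NA_character_
  key
}

#' Controlled vocabularies used across the package
#'
#' Boat types, gear types, habitat types and QC flag codes form closed
#' vocabularies: readers normalise case and whitespace but reject values
#' outside these sets.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
boat_types <- function() c("canoe", "motor", "shore")

#' @rdname vocabularies
#' @export
gear_types <- function() {
  c("gill_net", "seine_net", "beach_seine", "hand_line", "long_line",
    "spearfishing", "trap", "gleaning")
}

#' @rdname vocabularies
#' @export
habitat_types <- function() c("reef", "fad", "deep", "shore", "mangrove")

#' @rdname vocabularies
#' @export
flag_codes <- function() {
  c("LENGTH_OOB", "COUNT_OOB", "WEIGHT_OOB", "PRICE_OOB",
    "FORMAT_ERROR", "INVALID_GEAR_HABITAT")
}

# equirectangular projection to km about a reference origin; adequate at
# trip scale in the tropics where the monitored fleet operates
#' Project geographic coordinates to a local planar frame
#'
#' Converts latitude/longitude (degrees) to x/y kilometres about a reference
#' origin using an equirectangular approximation:
#' `x = (lon - lon0) * cos(lat0) * 111.32`, `y = (lat - lat0) * 110.57`.
#' Positional error is negligible over the few-kilometre scale of a fishing
#' trip at low latitudes.
#'
#' @param lat,lon Numeric vectors of coordinates in decimal degrees.
#' @param origin Named numeric vector `c(lat = , lon = )`.
#' @return A two-column matrix with columns `x_km`, `y_km`.
#' @export
local_xy <- function(lat, lon, origin) {
  stopifnot(all(c("lat", "lon") %in% names(origin)))
  x <- (lon - origin[["lon"]]) * cos(origin[["lat"]] * pi / 180) * 111.32
  y <- (lat - origin[["lat"]]) * 110.57
  cbind(x_km = x, y_km = y)
}

# inverse of local_xy, used by the simulator to place tracks on the globe
xy_to_lonlat <- function(x_km, y_km, origin) {
  lon <- origin[["lon"]] + x_km / (cos(origin[["lat"]] * pi / 180) * 111.32)
  lat <- origin[["lat"]] + y_km / 110.57
  cbind(lon = lon, lat = lat)
}
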