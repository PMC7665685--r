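#' Read a species parameter table
#'
#' The species table supplies the per-taxon length-weight coefficients and
#' plausibility bounds used by [estimate_weight()] and [apply_filters()].
#' Coefficients follow the FishBase convention: fork length in centimetres,
#' weight in grams, so that `W_g = a * L_cm^b`.
#'
#' Required columns: `taxon_code`, `name`, `a`, `b`, `length_min_cm`,
#' `length_max_cm`, `price_min`, `price_max`. Extra columns are kept.
#'
#' @param path Path to a CSV file.
#' @return A tibble validated against the species invariants.
#' @export
read_species <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_species(tbl)
}

#' @rdname read_species
#' @param species A data frame to validate in place.
#' @export
validate_species <- function(species) {
  required <- c("taxon_code", "name", "a", "b", "length_min_cm",
                "length_max_cm", "price_min", "price_max")
  missing <- setdiff(required, names(species))
  if (length(missing) > 0) {
    abort_ssf("species table is missing column(s): ",
              paste(missing, collapse = ", "))
  }
  species <- tibble::as_tibble(species)
  if (anyDuplicated(species$taxon_code)) {
    abort_ssf("species table has duplicated taxon_code values")
  }
  with(species, {
    if (any(a <= 0)) abort_ssf("length-weight coefficient a must be positive")
    if (any(b < 1 | b > 5)) {
      abort_ssf("allometric exponent b outside the plausible range [1, 5]")
    }
    if (any(length_min_cm >= length_max_cm)) {
      abort_ssf("length_min_cm must be strictly below length_max_cm")
    }
  })
  species
}

#' Gear x habitat validity matrix
#'
#' A boolean table saying which habitat types are plausible for each gear
#' type (e.g. gleaning happens on foot in the intertidal, never in deep
#' water). Trips recorded with an invalid combination are flagged
#' `INVALID_GEAR_HABITAT` by [apply_filters()]. The default matrix ships as
#' an editable CSV in `inst/extdata/gear_habitat_matrix.csv`; sites can
#' supply their own via `read_gear_habitat_matrix()`.
#'
#' @param path CSV with a `gear` column plus one logical column per habitat.
#' @return A tibble with a `gear` column and one logical column per habitat.
#' @export
read_gear_habitat_matrix <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_gear_habitat_matrix(tbl)
}

#' @rdname read_gear_habitat_matrix
#' @export
default_gear_habitat_matrix <- function() {
  path <- system.file("extdata", "gear_habitat_matrix.csv",
                      package = "ssfmonitor", mustWork = TRUE)
  read_gear_habitat_matrix(path)
}

validate_gear_habitat_matrix <- function(matrix) {
  if (!"gear" %in% names(matrix)) {
    abort_ssf("gear/habitat matrix must have a 'gear' column")
  }
  habitats <- setdiff(names(matrix), "gear")
  if (!all(habitats %in% habitat_types())) {
    abort_ssf("unknown habitat column(s) in gear/habitat matrix: ",
              paste(setdiff(habitats, habitat_types()), collapse = ", "))
  }
  matrix <- tibble::as_tibble(matrix)
  matrix[habitats] <- lapply(matrix[habitats], as.logical)
  valid_counts <- rowSums(as.matrix(matrix[habitats]))
  if (any(valid_counts < 1)) {
    abort_ssf("every gear needs at least one valid habitat; offending gear: ",
              paste(matrix$gear[valid_counts < 1], collapse = ", "))
  }
  matrix
}

# vectorized lookup: TRUE where the (gear, habitat) pair is valid; unknown
# gears or habitats are treated as invalid
gear_habitat_valid <- function(matrix, gear, habitat) {
  long <- tidyr::pivot_longer(matrix, -"gear", names_to = "habitat",
                              values_to = "valid")
  key <- paste(long$gear, long$habitat, sep = "\r")
  lookup <- setNames(long$valid, key)
  out <- unname(lookup[paste(gear, habitat, sep = "\r")])
  out[is.na(out)] <- FALSE
  out
}

#' Read a fleet census table
#'
#' National boat counts per boat type, the raising factor `N_b` in the
#' national catch estimator.
#'
#' @param path CSV with columns `boat_type`, `n_boats`.
#' @return A tibble with normalised boat types and integer counts.
#' @export
read_census <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_census(tbl)
}

#' @rdname read_census
#' @param census A data frame to validate in place.
#' @export
validate_census <- function(census) {
  if (!all(c("boat_type", "n_boats") %in% names(census))) {
    abort_ssf("census table needs columns boat_type, n_boats")
  }
  census <- tibble::as_tibble(census)
  census$boat_type <- normalize_enum(census$boat_type, boat_types())
  if (anyNA(census$boat_type)) abort_ssf("census has unknown boat_type values")
  if (any(census$n_boats < 0)) abort_ssf("census counts must be >= 0")
  census$n_boats <- as.integer(census$n_boats)
  census
}
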