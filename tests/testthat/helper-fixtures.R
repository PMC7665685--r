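# Hand-built fixtures shared across test files. Everything is constructed in
# code; CSV fixtures are written to tempfiles through the same writers users
# would call.

toy_species <- function() {
  tibble::tibble(
    taxon_code = c("AAA", "BBB"),
    name = c("Toy snapper", "Toy mackerel"),
    a = c(0.01, 0.0137),
    b = c(3, 3.07),
    length_min_cm = c(5, 10),
    length_max_cm = c(50, 80),
    price_min = c(1, 2),
    price_max = c(10, 15)
  )
}

# one flat landings row with overridable fields
flat_row <- function(...) {
  row <- list(trip_id = "T1", site = "Beco", municipality = "Covalima",
              date = "2018-05-10", boat_type = "motor", gear = "hand line",
              habitat = "FAD", n_fishers = 2, duration_h = 5,
              taxon_code = "AAA", fork_length_cm = 20, n_individuals = 2,
              price = 5, price_basis = "per_kg", unit_id = "U1")
  utils::modifyList(row, list(...))
}

landings_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  df <- dplyr::bind_rows(lapply(rows, function(r) {
    tibble::as_tibble(lapply(r, as.character))
  }))
  readr::write_csv(df, path, na = "", progress = FALSE)
  path
}

read_toy <- function(rows, species = toy_species()) {
  read_landings(landings_csv(rows), species)
}

# ping CSV for read_tracks tests
pings_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path, progress = FALSE)
  path
}

# small synthetic fishery used by several files; coarse GPS cadence keeps it
# fast while leaving >200 pings per track
small_fishery <- function(seed = 11, ...) {
  make_fishery(fishery_config(fleet = c(canoe = 4, motor = 3),
                              cadence_s = 60, ...), seed = seed)
}
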