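#' Estimate catch weight from fork length
#'
#' Applies the length-weight allometry `W_g = a * L_cm^b` (FishBase
#' convention: length in cm, weight in g) and scales by the number of
#' individuals, returning kilograms:
#' `weight_kg = n * a * length_cm^b / 1000`.
#'
#' @param length_cm Fork length in centimetres (positive).
#' @param n Number of individuals (positive integer); default 1.
#' @param a,b Length-weight coefficients for the taxon.
#' @return Estimated weight in kg, vectorised over all arguments; `NA`
#'   inputs give `NA` weights.
#' @examples
#' estimate_weight(10, 1, a = 0.01, b = 3) # 10 g = 0.01 kg
#' @export
estimate_weight <- function(length_cm, n = 1, a, b) {
  if (any(a <= 0, na.rm = TRUE)) abort_ssf("coefficient a must be positive")
  if (any(b < 1 | b > 5, na.rm = TRUE)) {
    abort_ssf("allometric exponent b outside [1, 5]")
  }
  if (any(length_cm < 0, na.rm = TRUE)) {
    abort_ssf("fork length must be nonnegative")
  }
  if (any(n < 1, na.rm = TRUE)) abort_ssf("count n must be >= 1")
  n * a * length_cm^b / 1000
}

#' Attach estimated weights to landing records
#'
#' Joins the species parameter table by `taxon_code` and fills
#' `est_weight_kg`. Records whose taxon is absent from the table keep an
#' `NA` weight; [apply_filters()] will flag them `FORMAT_ERROR`.
#'
#' @param x A `landings_data` object.
#' @param species Species table (see [read_species()]).
#' @return `x` with `est_weight_kg` populated.
#' @export
add_weights <- function(x, species) {
  stopifnot(inherits(x, "landings_data"))
  species <- validate_species(species)
  idx <- match(x$landings$taxon_code, species$taxon_code)
  a <- species$a[idx]
  b <- species$b[idx]
  known <- !is.na(idx)
  w <- rep(NA_real_, nrow(x$landings))
  if (any(known)) {
    w[known] <- estimate_weight(x$landings$fork_length_cm[known],
                                x$landings$n_individuals[known],
                                a[known], b[known])
  }
  x$landings$est_weight_kg <- w
  x
}

#' QC bound configuration
#'
#' Absolute plausibility thresholds used by [apply_filters()] alongside the
#' per-taxon length and price bounds in the species table. The defaults are
#' deliberately permissive — they are meant to catch data-entry errors
#' (an extra digit, a swapped field), not unusual fishing days.
#'
#' @param count_max Maximum credible number of individuals on a single
#'   landing record; default 1000 (large seine hauls of small schooling
#'   fish are counted in the hundreds).
#' @param weight_max_kg Maximum credible estimated weight (kg) of a single
#'   landing record; default 500.
#' @return A list of class `qc_bounds`.
#' @export
qc_bounds <- function(count_max = 1000, weight_max_kg = 500) {
  stopifnot(count_max >= 1, weight_max_kg > 0)
  structure(list(count_max = count_max, weight_max_kg = weight_max_kg),
            class = "qc_bounds")
}

#' Flag suspect landing records
#'
#' The flag-and-suppress QC engine. Each rule is evaluated independently and
#' a record accumulates every flag it earns; flags mark records as suppressed
#' but never delete them, so a curator can inspect and amend. Rules:
#'
#' * `LENGTH_OOB` — fork length outside the taxon's plausible range;
#' * `COUNT_OOB` — individual count below 1 or above `bounds$count_max`;
#' * `WEIGHT_OOB` — estimated record weight above `bounds$weight_max_kg`;
#' * `PRICE_OOB` — implied per-kg price outside the taxon's price band
#'   (per-fish prices are converted using the record's estimated weight);
#' * `FORMAT_ERROR` — unknown taxon, missing weight, or non-positive
#'   length/count/duration/fisher numbers;
#' * `INVALID_GEAR_HABITAT` — the trip reports a gear/habitat combination
#'   the validity matrix rules out; this trip-level flag propagates to every
#'   landing of the trip.
#'
#' Re-running the filters recomputes flags from scratch, so the operation is
#' idempotent. QC never hard-fails on data content.
#'
#' @param x A `landings_data` object with weights attached.
#' @param species Species parameter table.
#' @param matrix Gear/habitat validity matrix; default the shipped one.
#' @param bounds A [qc_bounds()] configuration.
#' @return `x` with the `flags` list-column set on landings and a logical
#'   `gear_habitat_valid` column on trips.
#' @export
apply_filters <- function(x, species,
                          matrix = default_gear_habitat_matrix(),
                          bounds = qc_bounds()) {
  stopifnot(inherits(x, "landings_data"))
  species <- validate_species(species)
  l <- x$landings
  t <- x$trips

  t$gear_habitat_valid <- gear_habitat_valid(matrix, t$gear, t$habitat)
  trip_format_bad <- is.na(t$duration_h) | t$duration_h <= 0 |
    is.na(t$n_fishers) | t$n_fishers < 1
  trip_idx <- match(l$trip_id, t$trip_id)

  sp_idx <- match(l$taxon_code, species$taxon_code)
  known <- !is.na(sp_idx)

  length_oob <- known &
    (l$fork_length_cm < species$length_min_cm[sp_idx] |
       l$fork_length_cm > species$length_max_cm[sp_idx])
  count_oob <- l$n_individuals < 1 | l$n_individuals > bounds$count_max
  weight_oob <- !is.na(l$est_weight_kg) &
    l$est_weight_kg > bounds$weight_max_kg

  # price plausibility is judged per kg: per-fish prices are converted via
  # the record's estimated per-fish weight when it is available
  per_kg <- ifelse(
    l$price_basis == "per_fish" & !is.na(l$est_weight_kg) & l$est_weight_kg > 0,
    l$price * l$n_individuals / l$est_weight_kg,
    l$price)
  price_oob <- known & !is.na(per_kg) &
    (per_kg < species$price_min[sp_idx] | per_kg > species$price_max[sp_idx])

  format_error <- !known | is.na(l$est_weight_kg) |
    is.na(l$fork_length_cm) | l$fork_length_cm <= 0 |
    is.na(l$n_individuals) | l$n_individuals < 1 |
    is.na(trip_idx) | trip_format_bad[trip_idx]
  invalid_gh <- !is.na(trip_idx) & !t$gear_habitat_valid[trip_idx]

  rule_matrix <- cbind(
    LENGTH_OOB = length_oob %in% TRUE,
    COUNT_OOB = count_oob %in% TRUE,
    WEIGHT_OOB = weight_oob %in% TRUE,
    PRICE_OOB = price_oob %in% TRUE,
    FORMAT_ERROR = format_error %in% TRUE,
    INVALID_GEAR_HABITAT = invalid_gh %in% TRUE
  )
  l$flags <- apply(rule_matrix, 1, function(r) colnames(rule_matrix)[r],
                   simplify = FALSE)

  x$landings <- l
  x$trips <- t
  x
}

#' Split a QC'd dataset into a clean store and a flagged report
#'
#' Flagged records are suppressed from downstream analytics but retained in
#' the report for curation. Landings with any flag are removed from the
#' clean set record-by-record; trips flagged `INVALID_GEAR_HABITAT` are
#' removed entirely (their reported effort is as unreliable as their catch),
#' while other trips remain even if all their landings were suppressed, so
#' their fishing effort still counts.
#'
#' @param x A `landings_data` object after [apply_filters()].
#' @return A list with `clean` (a `landings_data`) and `report` (a tibble
#'   with one row per flag: `record_id`, `trip_id`, `flag`, `field`,
#'   `value`).
#' @export
suppress_flagged <- function(x) {
  stopifnot(inherits(x, "landings_data"))
  if (!"gear_habitat_valid" %in% names(x$trips)) {
    abort_ssf("run apply_filters() before suppress_flagged()")
  }
  l <- x$landings
  flagged <- lengths(l$flags) > 0

  field_of <- c(LENGTH_OOB = "fork_length_cm", COUNT_OOB = "n_individuals",
                WEIGHT_OOB = "est_weight_kg", PRICE_OOB = "price",
                FORMAT_ERROR = "taxon_code",
                INVALID_GEAR_HABITAT = "gear/habitat")
  report <- purrr::map2_dfr(which(flagged), l$flags[flagged], function(i, fl) {
    tibble::tibble(
      record_id = l$record_id[i],
      trip_id = l$trip_id[i],
      flag = fl,
      field = unname(field_of[fl]),
      value = vapply(fl, function(f) {
        if (f == "INVALID_GEAR_HABITAT") {
          ti <- match(l$trip_id[i], x$trips$trip_id)
          paste(x$trips$gear[ti], x$trips$habitat[ti], sep = "/")
        } else {
          as.character(l[[field_of[[f]]]][i])
        }
      }, character(1))
    )
  })
  if (nrow(report) == 0) {
    report <- tibble::tibble(record_id = character(), trip_id = character(),
                             flag = character(), field = character(),
                             value = character())
  }

  clean_trips <- x$trips[x$trips$gear_habitat_valid, ]
  clean_landings <- l[!flagged & l$trip_id %in% clean_trips$trip_id, ]
  clean <- new_landings_data(clean_trips, clean_landings, x$parse_errors)
  list(clean = clean, report = report)
}
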