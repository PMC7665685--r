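#' Generate a synthetic species parameter table
#'
#' Draws `k` taxa with length-weight coefficients in realistic ranges
#' (`a` in 0.005–0.05, `b` in 2.7–3.3, the band where most fish allometries
#' fall) and internally consistent length and price plausibility bounds.
#' A `length_mean_cm` column records the typical fork length the trip
#' generator draws around.
#'
#' @param k Number of taxa.
#' @param seed Optional integer seed for reproducibility.
#' @return A species tibble passing [validate_species()].
#' @export
make_species <- function(k, seed = NULL) {
  stopifnot(k >= 1)
  if (!is.null(seed)) set.seed(seed)
  length_mean <- runif(k, 15, 60)
  tbl <- tibble::tibble(
    taxon_code = sprintf("SYN%02d", seq_len(k)),
    name = paste("Synthetic taxon", seq_len(k)),
    a = runif(k, 0.005, 0.05),
    b = runif(k, 2.7, 3.3),
    length_mean_cm = round(length_mean, 1),
    length_min_cm = round(pmax(1, 0.25 * length_mean), 1),
    length_max_cm = round(3 * length_mean, 1),
    price_min = round(runif(k, 0.5, 2), 2),
    price_max = round(runif(k, 8, 20), 2)
  )
  validate_species(tbl)
}

#' Configuration of the synthetic fishery
#'
#' Bundles every dial of [make_fishery()] with defaults describing a small
#' coastal fleet: canoes and motorboats making a handful of trips per month
#' to gear-specific fishing grounds, tracked at a 5-second GPS cadence.
#' Grounds are Gaussian patches keyed to gear (and through gear, to
#' habitat): `ground_separation_km` sets the distance between patch centres
#' and `ground_spread_km` the within-patch scatter of individual trips,
#' which together control how separable gears are for the trip classifier.
#'
#' @param fleet Named integer vector of boats per boat type.
#' @param month Calendar month simulated, `"YYYY-MM"`.
#' @param trips_per_boat Trips each boat makes in the month (the true VAC).
#' @param gear_by_boat Named list: gears available to each boat type.
#' @param gear_habitat Named character: the habitat each gear works.
#' @param mean_cpue Named numeric: mean catch rate (kg per fisher-hour) per
#'   gear.
#' @param catch_cv Lognormal coefficient of variation of trip catch around
#'   its gear mean.
#' @param duration_mean_h Mean trip duration (hours).
#' @param duration_sdlog Lognormal sd of trip duration; ignored when
#'   `constant_effort = TRUE`.
#' @param constant_effort If `TRUE`, every trip lasts exactly
#'   `duration_mean_h` with 2 fishers, making median and mean effort
#'   coincide (useful for exact estimator checks).
#' @param fishers_by_boat Named list of crew sizes per boat type; a scalar
#'   fixes the crew (the default: trip-to-trip effort variation then enters
#'   only through duration, so effort is lognormal), a vector is sampled.
#' @param base_lat,base_lon Harbour coordinates (decimal degrees).
#' @param ground_separation_km Distance between adjacent ground centres.
#' @param ground_spread_km SD of a trip's fishing spot around its ground.
#' @param cadence_s GPS ping interval in seconds.
#' @param gps_jitter_km Per-ping positional noise SD.
#' @param tracked_fraction Fraction of trips carrying a tracker.
#' @param unlabelled_fraction Fraction of tracked trips that are
#'   tracked-only (no enumerator record), the classifier's query population.
#' @param flag_rate Fraction of landing records corrupted with an injected
#'   QC error.
#' @param invalid_trip_rate Fraction of trips given an invalid gear/habitat
#'   combination.
#' @param n_species Number of synthetic taxa.
#' @param bounds [qc_bounds()] the injected errors are calibrated against.
#' @return A list of class `fishery_config`.
#' @export
fishery_config <- function(fleet = c(canoe = 12, motor = 8),
                           month = "2018-05",
                           trips_per_boat = 4,
                           gear_by_boat = list(canoe = c("gill_net", "hand_line"),
                                               motor = c("long_line", "trap")),
                           gear_habitat = c(gill_net = "reef",
                                            hand_line = "fad",
                                            long_line = "deep",
                                            trap = "mangrove"),
                           mean_cpue = c(gill_net = 1.5, hand_line = 1.0,
                                         long_line = 2.0, trap = 0.8),
                           catch_cv = 0.3,
                           duration_mean_h = 4,
                           duration_sdlog = 0.05,
                           constant_effort = FALSE,
                           fishers_by_boat = list(canoe = 2, motor = 3),
                           base_lat = -8.55, base_lon = 125.55,
                           ground_separation_km = 5,
                           ground_spread_km = 0.02,
                           cadence_s = 5,
                           gps_jitter_km = 0.005,
                           tracked_fraction = 1,
                           unlabelled_fraction = 0,
                           flag_rate = 0,
                           invalid_trip_rate = 0,
                           n_species = 6,
                           bounds = qc_bounds()) {
  cfg <- as.list(environment())
  gears <- unique(unlist(cfg$gear_by_boat))
  missing_ground <- setdiff(gears, names(cfg$gear_habitat))
  if (length(missing_ground) > 0) {
    abort_ssf("gear(s) without a fishing ground/habitat: ",
              paste(missing_ground, collapse = ", "))
  }
  if (!all(gears %in% names(cfg$mean_cpue))) {
    abort_ssf("mean_cpue missing for some gears")
  }
  if (!all(names(cfg$fleet) %in% boat_types())) {
    abort_ssf("unknown boat types in fleet")
  }
  structure(cfg, class = "fishery_config")
}

# day-one POSIXct of the configured month, UTC
month_start <- function(month) {
  as.POSIXct(paste0(month, "-01 00:00:00"), tz = "UTC")
}

#' Simulate a complete synthetic fishery with known ground truth
#'
#' Generates trips, landings, 5-second GPS tracks, a fleet census and a
#' truth record for one calendar month, under one master seed. All
#' randomness flows through named substreams (species, trips, tracks,
#' flags), so e.g. changing the flag-injection rate leaves the generated
#' trips untouched.
#'
#' Trips run out-and-back from the harbour to the gear's fishing ground
#' (10% of the trip travelling out, 80% fishing on the spot, 10%
#' returning), pinging every `cadence_s` seconds with GPS jitter. Landing
#' records draw fork lengths per taxon (lognormal, clipped inside the
#' plausibility bounds), counts sized to hit the gear's mean CPUE, and
#' per-kg prices inside the taxon band — so an uncorrupted record never
#' trips a QC rule, and every injected corruption does.
#'
#' @param config A [fishery_config()].
#' @param seed Master integer seed.
#' @return A list: `landings` (a `landings_data` of enumerator-observed
#'   trips), `tracks` (segmented ping tibble), `census`, `species`,
#'   `truth` (list: totals, per-type catch, true VAC, grounds, injected
#'   flags, trip/track link table, track labels) and `config`.
#' @export
make_fishery <- function(config = fishery_config(), seed = 1) {
  stopifnot(inherits(config, "fishery_config"))
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max, 4)
  species <- make_species(config$n_species, seed = sub[1])

  gears <- names(config$gear_habitat)
  g <- length(gears)
  grounds <- tibble::tibble(
    gear = gears,
    habitat = unname(config$gear_habitat[gears]),
    x_km = (seq_len(g) - (g + 1) / 2) * config$ground_separation_km,
    y_km = 6
  )
  ll <- xy_to_lonlat(grounds$x_km, grounds$y_km,
                     c(lat = config$base_lat, lon = config$base_lon))
  grounds$lon <- ll[, "lon"]
  grounds$lat <- ll[, "lat"]

  ## ---- trips ----
  set.seed(sub[2])
  t0 <- month_start(config$month)
  boat_rows <- purrr::imap_dfr(config$fleet, function(n, bt) {
    if (n == 0) return(NULL)
    tibble::tibble(
      unit_id = sprintf("%s%02d", toupper(substr(bt, 1, 1)), seq_len(n)),
      boat_type = bt)
  })
  trips <- purrr::pmap_dfr(boat_rows, function(unit_id, boat_type) {
    k <- config$trips_per_boat
    days <- sort(sample.int(28, k))
    gear <- sample(config$gear_by_boat[[boat_type]], k, replace = TRUE)
    crew <- config$fishers_by_boat[[boat_type]]
    n_fishers <- if (config$constant_effort) rep(2L, k) else
      as.integer(sample(rep(crew, 2), k, replace = TRUE))
    duration_h <- if (config$constant_effort) rep(config$duration_mean_h, k)
      else rlnorm(k, log(config$duration_mean_h) - config$duration_sdlog^2 / 2,
                  config$duration_sdlog)
    tibble::tibble(unit_id = unit_id, boat_type = boat_type,
                   date = as.Date(t0) + days - 1, gear = gear,
                   n_fishers = n_fishers, duration_h = duration_h)
  })
  trips$habitat <- unname(config$gear_habitat[trips$gear])
  # the habitat a trip actually fished, immune to later error injection:
  # this is what classifier validation scores against
  trips$true_habitat <- trips$habitat
  trips$trip_id <- sprintf("T%04d", seq_len(nrow(trips)))
  trips$site <- "Synthville"
  trips$municipality <- "Synthetica"
  trips$tracked <- runif(nrow(trips)) < config$tracked_fraction
  trips$unlabelled <- trips$tracked &
    runif(nrow(trips)) < config$unlabelled_fraction

  ## ---- landings ----
  landings <- purrr::pmap_dfr(
    trips[, c("trip_id", "gear", "n_fishers", "duration_h")],
    function(trip_id, gear, n_fishers, duration_h) {
      n_rec <- sample(1:3, 1)
      effort <- duration_h * n_fishers
      target <- config$mean_cpue[[gear]] * effort *
        rlnorm(1, -config$catch_cv^2 / 2, config$catch_cv)
      si <- sample.int(nrow(species), n_rec, replace = TRUE)
      len <- rlnorm(n_rec, log(species$length_mean_cm[si]), 0.15)
      len <- round(pmin(pmax(len, species$length_min_cm[si] + 0.5),
                        species$length_max_cm[si] - 0.5))
      w1 <- species$a[si] * len^species$b[si] / 1000
      tibble::tibble(
        trip_id = trip_id,
        taxon_code = species$taxon_code[si],
        fork_length_cm = len,
        n_individuals = pmax(1L, as.integer(round(target / n_rec / w1))),
        price = round(runif(n_rec, species$price_min[si] * 1.1,
                            species$price_max[si] * 0.9), 2),
        price_basis = "per_kg")
    })
  landings$record_id <- sprintf("R%05d", seq_len(nrow(landings)))
  landings$true_weight_kg <- estimate_weight(
    landings$fork_length_cm, landings$n_individuals,
    species$a[match(landings$taxon_code, species$taxon_code)],
    species$b[match(landings$taxon_code, species$taxon_code)])

  ## ---- truth bookkeeping (before corruption) ----
  by_trip <- dplyr::summarise(dplyr::group_by(landings, .data$trip_id),
                              catch_kg = sum(.data$true_weight_kg),
                              .groups = "drop")
  trips$catch_kg <- by_trip$catch_kg[match(trips$trip_id, by_trip$trip_id)]
  catch_by_type <- dplyr::summarise(dplyr::group_by(trips, .data$boat_type),
                                    catch_kg = sum(.data$catch_kg),
                                    .groups = "drop")

  ## ---- flag injection ----
  set.seed(sub[4])
  observed_trips <- trips$trip_id[!trips$unlabelled]
  obs_rec <- which(landings$trip_id %in% observed_trips)
  n_inj <- round(config$flag_rate * length(obs_rec))
  injected <- tibble::tibble(record_id = character(), flag = character())
  if (n_inj > 0) {
    pick <- sort(sample(obs_rec, n_inj))
    types <- sample(c("LENGTH_OOB", "COUNT_OOB", "WEIGHT_OOB", "PRICE_OOB",
                      "FORMAT_ERROR"), n_inj, replace = TRUE)
    heavy <- which.max(species$a * (0.95 * species$length_max_cm)^species$b)
    for (i in seq_len(n_inj)) {
      r <- pick[i]
      si <- match(landings$taxon_code[r], species$taxon_code)
      switch(types[i],
        LENGTH_OOB = {
          landings$fork_length_cm[r] <- species$length_max_cm[si] * 2
        },
        COUNT_OOB = {
          landings$n_individuals[r] <- as.integer(config$bounds$count_max * 2)
        },
        WEIGHT_OOB = {
          # heaviest plausible fish, in enough numbers to exceed the bound
          # while the length itself stays inside its species band
          landings$taxon_code[r] <- species$taxon_code[heavy]
          landings$fork_length_cm[r] <-
            round(species$length_max_cm[heavy] * 0.95)
          w1 <- species$a[heavy] *
            landings$fork_length_cm[r]^species$b[heavy] / 1000
          landings$n_individuals[r] <-
            as.integer(ceiling(1.1 * config$bounds$weight_max_kg / w1))
        },
        PRICE_OOB = {
          landings$price[r] <- species$price_max[si] * 3
        },
        FORMAT_ERROR = {
          landings$taxon_code[r] <- "UNK999"
        })
    }
    injected <- tibble::tibble(record_id = landings$record_id[pick],
                               flag = types)
  }

  n_bad_trips <- round(config$invalid_trip_rate * length(observed_trips))
  if (n_bad_trips > 0) {
    bad <- sample(observed_trips, n_bad_trips)
    matrix <- default_gear_habitat_matrix()
    for (tid in bad) {
      ti <- match(tid, trips$trip_id)
      row <- matrix[matrix$gear == trips$gear[ti], ]
      invalid_h <- habitat_types()[!as.logical(row[1, habitat_types()])]
      trips$habitat[ti] <- invalid_h[1]
    }
    injected <- dplyr::bind_rows(
      injected,
      tibble::tibble(
        record_id = landings$record_id[landings$trip_id %in% bad],
        flag = "INVALID_GEAR_HABITAT"))
  }

  clean_ids <- setdiff(landings$record_id[obs_rec], injected$record_id)
  clean_catch_kg <- sum(landings$true_weight_kg[
    landings$record_id %in% clean_ids])

  ## ---- tracks ----
  set.seed(sub[3])
  tracked <- trips[trips$tracked, ]
  ping_list <- purrr::pmap(
    tracked[, c("trip_id", "unit_id", "boat_type", "date", "gear",
                "duration_h")],
    function(trip_id, unit_id, boat_type, date, gear, duration_h) {
      gi <- match(gear, grounds$gear)
      spot <- c(grounds$x_km[gi], grounds$y_km[gi]) +
        rnorm(2, 0, config$ground_spread_km)
      total_s <- duration_h * 3600
      tt <- seq(0, total_s, by = config$cadence_s)
      frac <- tt / total_s
      # piecewise out / fish / back profile along the harbour->spot line
      amp <- ifelse(frac < 0.1, frac / 0.1,
                    ifelse(frac > 0.9, (1 - frac) / 0.1, 1))
      x <- spot[1] * amp + rnorm(length(tt), 0, config$gps_jitter_km)
      y <- spot[2] * amp + rnorm(length(tt), 0, config$gps_jitter_km)
      ll <- xy_to_lonlat(x, y, c(lat = config$base_lat,
                                 lon = config$base_lon))
      tibble::tibble(
        trip_id = trip_id, unit_id = unit_id, boat_type = boat_type,
        timestamp = as.POSIXct(date, tz = "UTC") + 6 * 3600 + tt,
        lat = ll[, "lat"], lon = ll[, "lon"])
    })
  pings <- dplyr::bind_rows(ping_list)

  # the segmenter numbers a unit's tracks in time order, so the expected
  # track id of a trip is its date rank within its unit
  tracked <- dplyr::mutate(
    dplyr::group_by(tracked, .data$unit_id),
    track_id = sprintf("%s-%03d", .data$unit_id,
                       as.integer(rank(.data$date, ties.method = "first"))))
  tracked <- dplyr::ungroup(tracked)

  tracks <- if (nrow(pings) > 0) {
    segment_tracks(pings[, c("unit_id", "boat_type", "timestamp",
                             "lat", "lon")])
  } else {
    pings
  }

  ## ---- outputs ----
  observed <- trips[!trips$unlabelled, ]
  observed$n_fishers <- as.numeric(observed$n_fishers)
  landings_out <- landings[landings$trip_id %in% observed$trip_id, ]
  data <- new_landings_data(
    trips = observed[, c("trip_id", "site", "municipality", "date",
                         "boat_type", "gear", "habitat", "n_fishers",
                         "duration_h", "unit_id")],
    landings = tibble::tibble(
      record_id = landings_out$record_id,
      trip_id = landings_out$trip_id,
      taxon_code = landings_out$taxon_code,
      fork_length_cm = landings_out$fork_length_cm,
      n_individuals = as.numeric(landings_out$n_individuals),
      price = landings_out$price,
      price_basis = landings_out$price_basis,
      est_weight_kg = NA_real_,
      flags = rep(list(character()), nrow(landings_out))
    ))

  census <- tibble::tibble(boat_type = names(config$fleet),
                           n_boats = as.integer(config$fleet))

  truth <- list(
    month = config$month,
    total_catch_kg = sum(trips$catch_kg),
    clean_catch_kg = clean_catch_kg,
    catch_by_boat_type = catch_by_type,
    vac_true = config$trips_per_boat,
    grounds = grounds,
    injected_flags = injected,
    trip_tracks = tibble::tibble(
      trip_id = tracked$trip_id, track_id = tracked$track_id,
      unit_id = tracked$unit_id, boat_type = tracked$boat_type,
      gear = tracked$gear, habitat = tracked$true_habitat,
      unlabelled = tracked$unlabelled),
    labels = tibble::tibble(track_id = tracked$track_id,
                            gear = tracked$gear,
                            habitat = tracked$true_habitat)
  )

  list(landings = data, tracks = tracks, census = census, species = species,
       truth = truth, config = config)
}
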