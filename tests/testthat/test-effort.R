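test_that("trip effort is duration times crew", {
  trips <- tibble::tibble(duration_h = c(5, 1, 2.5), n_fishers = c(2, 1, 3))
  expect_equal(trip_effort(trips), c(10, 1, 7.5))
  expect_error(trip_effort(tibble::tibble(duration_h = 0, n_fishers = 2)))
})

test_that("cpue is the ratio of totals and zero-catch trips contribute effort", {
  x <- read_toy(list(
    flat_row(trip_id = "T1", fork_length_cm = 10, n_individuals = 1000,
             n_fishers = 2, duration_h = 5)))           # 10 kg / 10 fisher-h
  x <- apply_filters(x, toy_species())
  clean <- suppress_flagged(x)$clean
  expect_equal(cpue(clean, by = "boat_type")$cpue_kg_per_fisher_h, 1.0)

  # add a zero-catch trip of equal effort: CPUE halves
  zero_trip <- clean
  zero_trip$trips <- dplyr::bind_rows(
    clean$trips,
    dplyr::mutate(clean$trips, trip_id = "T2"))
  expect_equal(cpue(zero_trip, by = "boat_type")$cpue_kg_per_fisher_h, 0.5)
})

test_that("cpue matches a hand-coded group-and-sum oracle on 50+ trips", {
  f <- make_fishery(fishery_config(fleet = c(canoe = 8, motor = 6),
                                   tracked_fraction = 0), seed = 9)
  res <- run_parse(f$landings, f$species)
  got <- cpue(res$clean, by = c("month", "boat_type", "gear"))
  expect_gte(sum(got$n_trips), 50)

  l <- res$clean$landings
  t <- res$clean$trips
  key <- paste(format(t$date, "%Y-%m"), t$boat_type, t$gear)
  for (k in unique(key)) {
    tt <- t[key == k, ]
    catch <- sum(l$est_weight_kg[l$trip_id %in% tt$trip_id])
    effort <- sum(tt$duration_h * tt$n_fishers)
    row <- got[paste(got$month, got$boat_type, got$gear) == k, ]
    expect_equal(row$total_catch_kg, catch)
    expect_equal(row$cpue_kg_per_fisher_h, catch / effort)
  }
  # conservation across strata
  expect_equal(sum(got$total_catch_kg), sum(l$est_weight_kg))
  # mean-of-ratios variant differs in general but stays finite
  alt <- cpue(res$clean, by = "boat_type", method = "mean_of_ratios")
  expect_true(all(is.finite(alt$cpue_kg_per_fisher_h)))
})

test_that("effort-weighted spline reproduces constants and flattens to the weighted mean", {
  tm <- 1:12
  const <- smooth_cpue(tm, rep(2.5, 12), weights = runif(12, 1, 5), spar = 0.5)
  expect_equal(const$fitted, rep(2.5, 12), tolerance = 1e-6)

  set.seed(2)
  y <- c(1, 3, 2, 5, 4, 6, 5, 7, 6, 8, 7, 9)
  w <- runif(12, 1, 10)
  heavy <- smooth_cpue(tm, y, weights = w, spar = 2)
  wmean <- sum(w * y) / sum(w)
  # maximal smoothing approaches the effort-weighted linear fit; its mean
  # equals the weighted mean of the data
  expect_equal(sum(w * heavy$fitted) / sum(w), wmean, tolerance = 1e-3)
  expect_error(smooth_cpue(1:3, c(1, 2, 3)), "4")
})

test_that("spline tracks a linear trend within the noise level", {
  set.seed(7)
  tm <- 1:24
  trend <- 0.5 + 0.1 * tm
  y <- trend + rnorm(24, 0, 0.15)
  fit <- smooth_cpue(tm, y, weights = rep(1, 24))
  interior <- 5:20
  expect_true(all(abs(fit$fitted[interior] - trend[interior]) < 0.15 * 3))
})

test_that("vac counts trips per active boat per month", {
  f <- small_fishery()
  v <- vac(f$tracks)
  expect_equal(v$vac, rep(f$config$trips_per_boat, nrow(v)))

  # hand count on a mixed fixture
  starts <- dplyr::summarise(dplyr::group_by(f$tracks, track_id),
                             unit_id = dplyr::first(unit_id),
                             boat_type = dplyr::first(boat_type),
                             .groups = "drop")
  hand <- table(starts$boat_type) / tapply(starts$unit_id, starts$boat_type,
                                           function(u) length(unique(u)))
  expect_equal(v$vac, as.numeric(hand[v$boat_type]))

  # roster denominator: an idle instrumented boat dilutes the average
  roster <- dplyr::bind_rows(
    dplyr::distinct(f$tracks[, c("unit_id", "boat_type")]),
    tibble::tibble(unit_id = "C99", boat_type = "canoe"))
  v2 <- vac(f$tracks, roster = roster)
  n_canoe <- sum(roster$boat_type == "canoe")
  expect_equal(v2$vac[v2$boat_type == "canoe"],
               f$config$trips_per_boat * (n_canoe - 1) / n_canoe)
})

test_that("ept uses the exact median with the even-n convention", {
  t3 <- tibble::tibble(boat_type = "canoe", duration_h = c(2, 4, 9),
                       n_fishers = 1)
  expect_equal(ept(t3)$ept_fisher_h, 4)
  t2 <- tibble::tibble(boat_type = "canoe", duration_h = c(2, 4), n_fishers = 1)
  expect_equal(ept(t2)$ept_fisher_h, 3)

  set.seed(5)
  e <- runif(101, 1, 30)
  t101 <- tibble::tibble(boat_type = "motor", duration_h = e, n_fishers = 1)
  expect_equal(ept(t101)$ept_fisher_h, sort(e)[51])  # sort-and-pick oracle
  expect_error(ept(t101[0, ]))
})

test_that("national catch follows the raising identity and its symmetries", {
  cp <- tibble::tibble(boat_type = c("canoe", "motor"),
                       cpue_kg_per_fisher_h = c(1, 2))
  ep <- tibble::tibble(boat_type = c("canoe", "motor"),
                       ept_fisher_h = c(10, 8))
  vc <- tibble::tibble(boat_type = c("canoe", "motor"), vac = c(4, 6))
  cs <- tibble::tibble(boat_type = c("canoe", "motor"), n_boats = c(100, 50))
  fe <- national_catch(cp, ep, vc, cs)
  # hand: canoe 1*10*4*100*.001 = 4 t; motor 2*8*6*50*.001 = 4.8 t
  expect_equal(fe$catch_t, c(4, 4.8))
  expect_equal(attr(fe, "total_t"), 8.8)

  # linearity in the census count
  cs2 <- dplyr::mutate(cs, n_boats = n_boats * 2L)
  expect_equal(national_catch(cp, ep, vc, cs2)$catch_t, c(8, 9.6))
  # any zero component zeroes that type
  vc0 <- dplyr::mutate(vc, vac = c(0, 6))
  expect_equal(national_catch(cp, ep, vc0, cs)$catch_t[1], 0)
  # shore boats are ignored, missing components for raised types error
  cs3 <- dplyr::bind_rows(cs, tibble::tibble(boat_type = "shore",
                                             n_boats = 30L))
  expect_equal(attr(national_catch(cp, ep, vc, cs3), "total_t"), 8.8)
  expect_error(national_catch(cp[1, ], ep, vc, cs), "motor")
})

test_that("heat map bins conserve pings and respect symmetry", {
  t0 <- as.POSIXct("2018-05-10 06:00:00", tz = "UTC")
  one_spot <- tibble::tibble(track_id = "a", unit_id = "U1",
                             boat_type = "canoe",
                             timestamp = t0 + 1:25, lat = -8.5, lon = 125.5)
  g <- effort_heatmap(one_spot, cell_size_km = 1)
  expect_equal(dim(g$counts), c(1, 1))
  expect_equal(sum(g$counts), 25)

  # two clusters ~3 km apart along the x axis, equal sizes
  two <- dplyr::bind_rows(
    one_spot,
    dplyr::mutate(one_spot, lon = 125.5 + 3 / (111.32 * cos(-8.5 * pi / 180))))
  g2 <- effort_heatmap(two, cell_size_km = 1)
  expect_equal(sum(g2$counts), 50)
  expect_setequal(g2$counts[g2$counts > 0], c(25, 25))

  # uniform pings: cell counts within 3 SD of the multinomial expectation
  set.seed(8)
  n <- 4000
  unif <- tibble::tibble(track_id = "u", unit_id = "U", boat_type = "canoe",
                         timestamp = t0 + seq_len(n),
                         lat = -8.5 + runif(n) * 4 / 110.57,
                         lon = 125.5 + runif(n) * 4 /
                           (111.32 * cos(-8.5 * pi / 180)))
  g3 <- effort_heatmap(unif, cell_size_km = 1)
  expect_equal(sum(g3$counts), n)
  p <- 1 / length(g3$counts)
  expected <- n * p
  sd3 <- 3 * sqrt(n * p * (1 - p))
  expect_true(all(abs(g3$counts - expected) <= sd3))
})
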