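# straight-line synthetic track helper: n pings between two km offsets
line_track <- function(id, from, to, n = 20,
                       t0 = as.POSIXct("2018-05-10 06:00:00", tz = "UTC"),
                       origin = c(lat = -8.5, lon = 125.5)) {
  s <- seq(0, 1, length.out = n)
  x <- from[1] + s * (to[1] - from[1])
  y <- from[2] + s * (to[2] - from[2])
  lon <- origin[["lon"]] + x / (111.32 * cos(origin[["lat"]] * pi / 180))
  lat <- origin[["lat"]] + y / 110.57
  tibble::tibble(track_id = id, unit_id = id, boat_type = "canoe",
                 timestamp = t0 + s * 3600, lat = lat, lon = lon)
}

test_that("features reproduce the pings of a 10-ping track and collapse for a stationary one", {
  tr <- line_track("a", c(0, 0), c(9, 0), n = 10)
  f <- track_features(tr, origin = c(lat = -8.5, lon = 125.5))
  expect_equal(dim(f), c(1, 20))
  expect_equal(unname(f[1, seq(1, 20, 2)]), 0:9, tolerance = 1e-9)
  expect_equal(unname(f[1, seq(2, 20, 2)]), rep(0, 10), tolerance = 1e-9)

  still <- line_track("s", c(1, 2), c(1, 2), n = 30)
  fs <- track_features(still, origin = c(lat = -8.5, lon = 125.5))
  expect_equal(unname(fs[1, seq(1, 20, 2)]), rep(1, 10), tolerance = 1e-9)
  expect_equal(unname(fs[1, seq(2, 20, 2)]), rep(2, 10), tolerance = 1e-9)

  expect_error(track_features(still[1, ]), "2 pings")
})

test_that("interpolated features match a brute-force oracle on an irregular 100-ping track", {
  set.seed(12)
  t0 <- as.POSIXct("2018-05-10 06:00:00", tz = "UTC")
  tt <- sort(runif(100, 0, 7200))
  x <- cumsum(rnorm(100, 0.05, 0.02))
  y <- cumsum(rnorm(100, 0.02, 0.02))
  origin <- c(lat = -8.5, lon = 125.5)
  tr <- tibble::tibble(
    track_id = "z", unit_id = "z", boat_type = "motor",
    timestamp = t0 + tt,
    lat = origin[["lat"]] + y / 110.57,
    lon = origin[["lon"]] + x / (111.32 * cos(origin[["lat"]] * pi / 180)))
  f <- track_features(tr, origin = origin)

  # oracle: manual bracketing + linear interpolation at 10 even times
  at <- seq(tt[1], tt[100], length.out = 10)
  for (j in seq_len(10)) {
    hi <- which(tt >= at[j])[1]
    if (tt[hi] == at[j]) { ox <- x[hi]; oy <- y[hi] } else {
      lo <- hi - 1
      w <- (at[j] - tt[lo]) / (tt[hi] - tt[lo])
      ox <- x[lo] + w * (x[hi] - x[lo])
      oy <- y[lo] + w * (y[hi] - y[lo])
    }
    expect_equal(unname(f[1, 2 * j - 1]), ox, tolerance = 1e-9)
    expect_equal(unname(f[1, 2 * j]), oy, tolerance = 1e-9)
  }
})

test_that("donor assignment: self-match at distance 0, strict 0.20 km cutoff", {
  tracks <- dplyr::bind_rows(
    line_track("t1", c(0, 0), c(5, 0)),
    line_track("t2", c(0, 0), c(0, 5)),
    line_track("q1", c(0, 0), c(5, 0)))
  f <- track_features(tracks)
  labels <- tibble::tibble(track_id = c("t1", "t2"),
                           gear = c("hand_line", "gill_net"),
                           habitat = c("fad", "reef"))
  res <- assign_donor(f["q1", , drop = FALSE],
                      f[c("t1", "t2"), ], labels)
  expect_equal(res$donor_id, "t1")
  expect_equal(res$distance_km, 0)
  expect_equal(res$gear, "hand_line")
  expect_equal(res$habitat, "fad")

  # a query 0.25/sqrt(20) km off in every coordinate sits at exactly 0.25 km
  q <- f["q1", , drop = FALSE] + 0.25 / sqrt(20)
  rownames(q) <- "q2"
  res2 <- assign_donor(q, f[c("t1", "t2"), ], labels)
  expect_equal(res2$distance_km, 0.25, tolerance = 1e-12)
  expect_false(res2$assigned)
  expect_true(is.na(res2$gear))
})

test_that("donor assignment agrees with an exhaustive double-loop search", {
  f <- make_fishery(fishery_config(fleet = c(canoe = 7, motor = 6),
                                   cadence_s = 120,
                                   unlabelled_fraction = 0.3), seed = 21)
  feats <- track_features(f$tracks)
  linked <- f$truth$trip_tracks[!f$truth$trip_tracks$unlabelled, ]
  queries <- f$truth$trip_tracks$track_id[f$truth$trip_tracks$unlabelled]
  expect_gte(nrow(feats), 40)
  expect_gte(length(queries), 5)

  labels <- f$truth$labels[f$truth$labels$track_id %in% linked$track_id, ]
  res <- assign_donor(feats[queries, , drop = FALSE],
                      feats[linked$track_id, , drop = FALSE], labels)

  for (i in seq_along(queries)) {
    best <- Inf; best_id <- NA_character_
    for (d_id in sort(linked$track_id)) {
      dist <- sqrt(sum((feats[queries[i], ] - feats[d_id, ])^2))
      if (dist < best) { best <- dist; best_id <- d_id }
    }
    expect_equal(res$donor_id[i], best_id)
    expect_equal(res$distance_km[i], best, tolerance = 1e-12)
    expect_equal(res$assigned[i], best < 0.20)
  }
})

test_that("assignment rate is non-decreasing in the cutoff", {
  f <- make_fishery(fishery_config(fleet = c(canoe = 6, motor = 5),
                                   cadence_s = 120, gps_jitter_km = 0.02,
                                   unlabelled_fraction = 0.3), seed = 5)
  feats <- track_features(f$tracks)
  linked <- f$truth$trip_tracks[!f$truth$trip_tracks$unlabelled, ]
  queries <- f$truth$trip_tracks$track_id[f$truth$trip_tracks$unlabelled]
  labels <- f$truth$labels
  rates <- vapply(c(0.01, 0.05, 0.2, 1, 10), function(cut) {
    mean(assign_donor(feats[queries, , drop = FALSE],
                      feats[linked$track_id, , drop = FALSE],
                      labels, cutoff_km = cut)$assigned)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[5], 1)
})

test_that("feature distances are invariant to the reference origin at local scale", {
  f <- small_fishery(seed = 31)
  o1 <- c(lat = -8.55, lon = 125.55)
  o2 <- c(lat = -8.85, lon = 125.85)  # shifted ~0.3 degree
  f1 <- track_features(f$tracks, origin = o1)
  f2 <- track_features(f$tracks, origin = o2)
  d1 <- as.matrix(dist(f1))
  d2 <- as.matrix(dist(f2))
  keep <- d1 > 0
  expect_lt(max(abs(d1[keep] - d2[keep]) / d1[keep]), 0.001)
})

test_that("validation is seed-reproducible and near-perfect on separable grounds", {
  f <- make_fishery(fishery_config(fleet = c(canoe = 8, motor = 6),
                                   cadence_s = 60), seed = 13)
  feats <- track_features(f$tracks)
  labels <- f$truth$labels
  v1 <- validate_classifier(feats, labels, iterations = 20, seed = 99)
  v2 <- validate_classifier(feats, labels, iterations = 20, seed = 99)
  expect_identical(v1$per_iteration, v2$per_iteration)
  expect_gte(v1$summary$mean_accuracy[1], 0.95)
  expect_gte(v1$summary$mean_accuracy[2], 0.95)
})

test_that("random labels on well-separated clusters score at chance level", {
  set.seed(17)
  k <- 4
  n_per <- 15
  centers <- cbind(rep(seq(0, 30, by = 10), each = n_per), 0)
  feat <- matrix(rep(centers[, 1], each = 1), ncol = 1)
  feat <- cbind(feat + rnorm(k * n_per, 0, 0.01),
                matrix(rnorm(k * n_per * 19, 0, 0.01), ncol = 19))
  rownames(feat) <- sprintf("t%03d", seq_len(k * n_per))
  gears <- sample(gear_types()[1:k], k * n_per, replace = TRUE)
  habs <- sample(habitat_types()[1:k], k * n_per, replace = TRUE)
  labels <- tibble::tibble(track_id = rownames(feat), gear = gears,
                           habitat = habs)
  v <- validate_classifier(feat, labels, iterations = 50, seed = 3)
  expect_equal(v$summary$mean_accuracy[1], 1 / k, tolerance = 0.35)
  expect_equal(v$summary$mean_accuracy[2], 1 / k, tolerance = 0.35)
})
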