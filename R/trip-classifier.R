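#' Fixed-length trajectory features for trip matching
#'
#' Summarises each track as 10 positions sampled at evenly spaced times from
#' the first to the last ping, positions obtained by linear interpolation
#' between the bracketing pings and projected to kilometres about a common
#' reference origin. The result is a 20-dimensional feature vector
#' (x1, y1, ..., x10, y10) per trip, comparable across trips by Euclidean
#' distance. An alternative `"displacement"` encoding uses the 9 successive
#' displacement vectors between those positions (18 dimensions), which is
#' origin-free and emphasises movement pattern over location.
#'
#' @param tracks Ping tibble (`track_id`, `timestamp`, `lat`, `lon`).
#' @param origin Reference `c(lat = , lon = )`; defaults to the centroid of
#'   all pings. Feature *distances* are insensitive to this choice at local
#'   scale.
#' @param n_points Number of sampled positions per trip; default 10.
#' @param type `"position"` (default) or `"displacement"`.
#' @return Numeric matrix, one row per track (rownames = `track_id`), with
#'   `2 * n_points` (or `2 * (n_points - 1)`) columns; the origin and type
#'   are attached as attributes.
#' @export
track_features <- function(tracks, origin = NULL, n_points = 10,
                           type = c("position", "displacement")) {
  type <- match.arg(type)
  if (nrow(tracks) == 0) abort_ssf("no pings to extract features from")
  origin <- origin %||% c(lat = mean(tracks$lat), lon = mean(tracks$lon))

  ids <- sort(unique(tracks$track_id))
  feats <- vapply(ids, function(id) {
    p <- tracks[tracks$track_id == id, ]
    if (nrow(p) < 2) {
      abort_ssf("track ", id, " has fewer than 2 pings; cannot interpolate")
    }
    p <- p[order(p$timestamp), ]
    xy <- local_xy(p$lat, p$lon, origin)
    tt <- as.numeric(p$timestamp)
    at <- seq(tt[1], tt[length(tt)], length.out = n_points)
    x <- approx(tt, xy[, 1], xout = at, ties = "ordered")$y
    y <- approx(tt, xy[, 2], xout = at, ties = "ordered")$y
    if (type == "displacement") {
      as.vector(rbind(diff(x), diff(y)))
    } else {
      as.vector(rbind(x, y))
    }
  }, numeric(if (type == "displacement") 2 * (n_points - 1) else 2 * n_points))
  m <- t(feats)
  rownames(m) <- ids
  k <- ncol(m) / 2
  colnames(m) <- as.vector(rbind(paste0("x", seq_len(k)),
                                 paste0("y", seq_len(k))))
  if (anyNA(m) || any(!is.finite(m))) abort_ssf("non-finite feature values")
  attr(m, "origin") <- origin
  attr(m, "type") <- type
  m
}

# full Euclidean distance matrix between two feature matrices, computed
# via the expansion |q - t|^2 = |q|^2 + |t|^2 - 2 q.t
feature_distances <- function(query, training) {
  q2 <- rowSums(query^2)
  t2 <- rowSums(training^2)
  d2 <- outer(q2, rep(1, nrow(training))) +
    outer(rep(1, nrow(query)), t2) - 2 * tcrossprod(query, training)
  sqrt(pmax(d2, 0))
}

#' Assign donor trips by nearest-neighbour distance
#'
#' For each unlabelled (query) trip, finds the labelled (training) trip with
#' the minimum Euclidean distance in feature space and copies its gear and
#' habitat labels — but only when that distance is below `cutoff_km`
#' (default 0.20 km); more distant queries stay unassigned. Distance is the
#' full 20-dimensional norm of the feature difference. Ties are broken by
#' the lexicographically smallest donor id.
#'
#' @param query,training Feature matrices from [track_features()] built with
#'   the same origin and type.
#' @param labels Tibble with `track_id`, `gear`, `habitat` covering the
#'   training rows.
#' @param cutoff_km Maximum donor distance for assignment; default 0.20.
#' @return Tibble with one row per query: `query_id`, `donor_id`,
#'   `distance_km`, `assigned`, `gear`, `habitat` (labels `NA` when
#'   unassigned).
#' @export
assign_donor <- function(query, training, labels, cutoff_km = 0.20) {
  if (nrow(training) == 0) abort_ssf("training set is empty")
  if (ncol(query) != ncol(training)) {
    abort_ssf("query and training features have different dimensions")
  }
  if (!all(rownames(training) %in% labels$track_id)) {
    abort_ssf("labels missing for some training trips")
  }
  # lexicographic donor order makes which.min's first-match tie-break
  # deterministic: the lowest donor id wins
  training <- training[order(rownames(training)), , drop = FALSE]
  d <- feature_distances(query, training)
  j <- apply(d, 1, which.min)
  # the expansion trick above is fast but loses ~1e-12 relative precision;
  # recompute the winning distance directly
  dist_min <- unname(sqrt(rowSums((query - training[j, , drop = FALSE])^2)))
  donor <- rownames(training)[j]
  assigned <- dist_min < cutoff_km
  li <- match(donor, labels$track_id)
  tibble::tibble(
    query_id = rownames(query),
    donor_id = donor,
    distance_km = dist_min,
    assigned = assigned,
    gear = ifelse(assigned, labels$gear[li], NA_character_),
    habitat = ifelse(assigned, labels$habitat[li], NA_character_)
  )
}

#' Hold-out validation of nearest-neighbour trip classification
#'
#' Repeatedly splits the linked trips (those with both a GPS track and an
#' enumerator record) into training and query sets, runs [assign_donor()]
#' on the queries, and scores the fraction of gear and habitat labels
#' correctly recovered. Queries left unassigned (no donor within the
#' cutoff) count as incorrect. Defaults follow the standard protocol:
#' 80/20 split, 100 iterations.
#'
#' @param features Feature matrix of all linked trips.
#' @param labels Tibble `track_id`, `gear`, `habitat` for every linked trip.
#' @param train_frac Training fraction per split; default 0.8.
#' @param iterations Number of random splits; default 100.
#' @param cutoff_km Donor distance cutoff; default 0.20.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   per-iteration splits and results exactly.
#' @return A list: `summary` (mean and SD of accuracy per label, as
#'   proportions), `per_iteration` (accuracy and assignment counts per
#'   split), and `notes` (e.g. degenerate single-class labels).
#' @export
validate_classifier <- function(features, labels, train_frac = 0.8,
                                iterations = 100, cutoff_km = 0.20,
                                seed = NULL) {
  n <- nrow(features)
  if (n < 10) abort_ssf("need at least 10 linked trips to validate")
  labels <- labels[match(rownames(features), labels$track_id), ]
  if (anyNA(labels$gear) || anyNA(labels$habitat)) {
    abort_ssf("all linked trips must carry both gear and habitat labels")
  }
  notes <- character()
  for (lab in c("gear", "habitat")) {
    if (length(unique(labels[[lab]])) < 2) {
      notes <- c(notes, paste0("single ", lab, " class: accuracy is trivially ",
                               "high and uninformative"))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  n_train <- max(1L, min(n - 1L, round(train_frac * n)))

  per_iter <- purrr::map_dfr(seq_len(iterations), function(it) {
    idx <- sample.int(n, n_train)
    res <- assign_donor(features[-idx, , drop = FALSE],
                        features[idx, , drop = FALSE],
                        labels, cutoff_km = cutoff_km)
    truth <- labels[match(res$query_id, labels$track_id), ]
    tibble::tibble(
      iteration = it,
      n_query = nrow(res),
      n_assigned = sum(res$assigned),
      accuracy_gear = mean(res$assigned & res$gear == truth$gear,
                           na.rm = TRUE),
      accuracy_habitat = mean(res$assigned & res$habitat == truth$habitat,
                              na.rm = TRUE)
    )
  })
  summary <- tibble::tibble(
    label = c("gear", "habitat"),
    mean_accuracy = c(mean(per_iter$accuracy_gear),
                      mean(per_iter$accuracy_habitat)),
    sd_accuracy = c(stats::sd(per_iter$accuracy_gear),
                    stats::sd(per_iter$accuracy_habitat))
  )
  list(summary = summary, per_iteration = per_iter, notes = notes)
}
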