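#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean
#' Earth radius), the default metric for service-precinct construction.
#' Both arguments are recycled; each is a `(latitude, longitude)` pair in
#' decimal degrees WGS84, or a two-column matrix of such pairs.
#'
#' @param a,b Numeric `c(lat, lon)` vectors or two-column `[lat, lon]`
#'   matrices.
#' @return Distance(s) in kilometres.
#' @examples
#' great_circle_km(c(-26.2041, 28.0473), c(-25.7479, 28.2293)) # ~53.9
#' @export
great_circle_km <- function(a, b) {
  a <- to_latlon_matrix(a)
  b <- to_latlon_matrix(b)
  check_coordinates(a[, 1L], a[, 2L])
  check_coordinates(b[, 1L], b[, 2L])
  # geosphere expects [lon, lat] and metres
  geosphere::distHaversine(a[, 2:1, drop = FALSE], b[, 2:1, drop = FALSE],
                           r = 6371008.8) / 1000
}

#' Planar (equirectangular) distance between points
#'
#' Alternative metric: Euclidean distance after an equirectangular
#' projection about the mean latitude of the points involved. Provided
#' because published precinct maps are sometimes drawn with planar buffers
#' on projected coordinates; [great_circle_km()] is the package default.
#'
#' @inheritParams great_circle_km
#' @return Distance(s) in kilometres.
#' @export
planar_km <- function(a, b) {
  a <- to_latlon_matrix(a)
  b <- to_latlon_matrix(b)
  check_coordinates(a[, 1L], a[, 2L])
  check_coordinates(b[, 1L], b[, 2L])
  r <- 6371.0088
  lat0 <- mean(c(a[, 1L], b[, 1L])) * pi / 180
  dx <- (b[, 2L] - a[, 2L]) * pi / 180 * cos(lat0) * r
  dy <- (b[, 1L] - a[, 1L]) * pi / 180 * r
  sqrt(dx^2 + dy^2)
}

to_latlon_matrix <- function(p) {
  if (is.matrix(p) || is.data.frame(p)) {
    m <- as.matrix(p)[, 1:2, drop = FALSE]
  } else {
    m <- matrix(p, ncol = 2L, byrow = TRUE)
  }
  storage.mode(m) <- "double"
  m
}

# distance matrix (facilities x labs), km
distance_matrix_km <- function(fac, labs, metric = great_circle_km) {
  n <- nrow(fac); m <- nrow(labs)
  a <- cbind(rep(fac$latitude, times = m), rep(fac$longitude, times = m))
  b <- cbind(rep(labs$latitude, each = n), rep(labs$longitude, each = n))
  matrix(metric(a, b), nrow = n, ncol = m,
         dimnames = list(fac$id, labs$id))
}

#' Assign each facility to its nearest testing laboratory
#'
#' Nearest-neighbour assignment under great-circle (default) or planar
#' distance. A facility is `covered` when its assigned laboratory lies
#' within the schedule's service-precinct radius. Distance ties (within
#' 1e-9 km) are broken by the lexicographically smallest laboratory id, so
#' the assignment is deterministic.
#'
#' Capacity is not enforced here: the assignment records demand as it
#' falls, and [capacity_check()] reports where instruments are
#' over-committed.
#'
#' @param facilities A `facility_registry`.
#' @param labs A `laboratory_registry` of testing sites (at least one row).
#' @param schedule A [tier_schedule()]; supplies `radius_km`.
#' @param metric `"great_circle"` or `"planar"`.
#' @return A data.frame of class `assignment_table` with columns
#'   `facility_id, lab_id, distance_km, covered` and the metric recorded in
#'   attribute `"metric"`.
#' @export
assign_nearest <- function(facilities, labs, schedule = tier_schedule(),
                           metric = c("great_circle", "planar")) {
  schedule <- as_schedule(schedule)
  metric <- match.arg(metric)
  if (nrow(labs) < 1L) stop("laboratory registry is empty", call. = FALSE)
  fun <- if (metric == "great_circle") great_circle_km else planar_km
  d <- distance_matrix_km(facilities, labs, fun)
  # tie-break: among labs within 1e-9 km of the row minimum, smallest id
  ord <- order(labs$id)
  nearest <- apply(d[, ord, drop = FALSE], 1L, function(row) {
    ord[which(row <= min(row) + 1e-9)[1L]]
  })
  dist_km <- d[cbind(seq_len(nrow(facilities)), nearest)]
  out <- data.frame(
    facility_id = facilities$id,
    lab_id = labs$id[nearest],
    distance_km = dist_km,
    covered = dist_km <= schedule$radius_km,
    stringsAsFactors = FALSE
  )
  attr(out, "metric") <- metric
  attr(out, "radius_km") <- schedule$radius_km
  class(out) <- c("assignment_table", "data.frame")
  out
}

#' Summarize service coverage of an assignment
#'
#' Computes the covered fraction of facilities (and its volume-weighted
#' variant), lists uncovered facilities, summarizes assignment distances
#' per district, and flags pairs of laboratories lying within one precinct
#' radius of each other as over-service (consolidation) candidates.
#'
#' @param assignments Output of [assign_nearest()].
#' @param facilities,labs The registries used for the assignment.
#' @param schedule A [tier_schedule()].
#' @return A list of class `coverage_report`: `fraction_covered`,
#'   `fraction_covered_volume`, `uncovered_ids`, `district_distance`
#'   (per-district mean/max assignment distance and covered fraction), and
#'   `over_serviced_pairs`.
#' @export
coverage_report <- function(assignments, facilities, labs,
                            schedule = tier_schedule()) {
  schedule <- as_schedule(schedule)
  stopifnot(nrow(assignments) == nrow(facilities))
  idx <- match(assignments$facility_id, facilities$id)
  if (anyNA(idx)) stop("assignments reference unknown facility ids", call. = FALSE)
  vol <- facilities$annual_volume[idx]
  covered <- assignments$covered
  total_vol <- sum(vol)

  dd <- split(seq_len(nrow(assignments)), facilities$district_id[idx])
  district_distance <- data.frame(
    district_id = names(dd),
    n_facilities = vapply(dd, length, integer(1)),
    mean_distance_km = vapply(dd, function(i) mean(assignments$distance_km[i]),
                              numeric(1)),
    max_distance_km = vapply(dd, function(i) max(assignments$distance_km[i]),
                             numeric(1)),
    fraction_covered = vapply(dd, function(i) mean(covered[i]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )

  pairs <- data.frame(lab_a = character(), lab_b = character(),
                      distance_km = numeric(), stringsAsFactors = FALSE)
  if (nrow(labs) >= 2L) {
    dl <- distance_matrix_km(labs, labs)
    hit <- which(upper.tri(dl) & dl <= schedule$radius_km, arr.ind = TRUE)
    if (nrow(hit)) {
      pairs <- data.frame(lab_a = labs$id[hit[, 1L]],
                          lab_b = labs$id[hit[, 2L]],
                          distance_km = dl[hit], stringsAsFactors = FALSE)
    }
  }

  structure(list(
    fraction_covered = mean(covered),
    fraction_covered_volume = if (total_vol > 0)
      sum(vol[covered]) / total_vol else NA_real_,
    n_facilities = nrow(facilities),
    uncovered_ids = assignments$facility_id[!covered],
    district_distance = district_distance,
    over_serviced_pairs = pairs,
    radius_km = schedule$radius_km
  ), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Coverage at %g km precinct radius\n", x$radius_km))
  cat(sprintf("  facilities covered: %.1f%% (%d of %d uncovered)\n",
              100 * x$fraction_covered, length(x$uncovered_ids),
              x$n_facilities))
  cat(sprintf("  volume covered:     %.1f%%\n",
              100 * x$fraction_covered_volume))
  cat(sprintf("  over-serviced laboratory pairs within radius: %d\n",
              nrow(x$over_serviced_pairs)))
  invisible(x)
}

#' Export service precincts as GeoJSON circles
#'
#' Writes one 64-segment polygon per laboratory, approximating the
#' great-circle service precinct, for inspection in any GIS viewer.
#'
#' @param labs A `laboratory_registry`.
#' @param path Output `.geojson` path.
#' @param schedule A [tier_schedule()]; supplies the radius.
#' @return `path`, invisibly.
#' @export
write_precincts_geojson <- function(labs, path, schedule = tier_schedule()) {
  schedule <- as_schedule(schedule)
  features <- lapply(seq_len(nrow(labs)), function(i) {
    ring <- geosphere::destPoint(c(labs$longitude[i], labs$latitude[i]),
                                 b = seq(0, 360, length.out = 65),
                                 d = schedule$radius_km * 1000)
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) ring[j, ]))),
         properties = list(lab_id = labs$id[i],
                           radius_km = schedule$radius_km))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
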