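## The eight per-participant outdoor navigation variables: outing rates
## (total/day/night), time spent moving per outing, distances per outing
## (total, walking, mean from home), and mean pairwise discrete Frechet
## distance between outing trajectories.

profile_vars <- c("outings_per_day", "day_outings_per_day",
                  "night_outings_per_day", "moving_hours_per_outing",
                  "total_km_per_outing", "walking_km_per_outing",
                  "mean_km_from_home_per_outing", "mean_dfd")

#' Outing rates per recorded day
#'
#' @param outings Outing tibble with a `band` column.
#' @param recorded_days Number of days surviving [clean_days()] (>= 1).
#' @return Named list: `total`, `day`, `night` outings per day.
#' @export
outing_rates <- function(outings, recorded_days) {
  if (recorded_days < 1)
    stop("recorded_days must be >= 1 (profile undefined)", call. = FALSE)
  list(total = nrow(outings) / recorded_days,
       day = sum(outings$band == "day") / recorded_days,
       night = sum(outings$band == "night") / recorded_days)
}

#' Time spent moving during an outing
#'
#' Sums the sampling-time contribution of fixes whose window mode is not
#' stationary; recording gaps (the device stops when no movement is detected
#' for 2 minutes) contribute nothing by construction.
#'
#' @param outing_fixes Fix tibble of one outing with a `mode` column.
#' @param interval_s Sampling interval, s.
#' @return Hours moving.
#' @export
moving_time <- function(outing_fixes, interval_s) {
  moving <- !is.na(outing_fixes$mode) & outing_fixes$mode != "stationary"
  sum(moving) * interval_s / 3600
}

#' Distances of one outing
#'
#' Total path length (sum of consecutive geodesic distances), walking path
#' length (restricted to consecutive pairs whose fixes are both in by-foot
#' windows), and mean distance of the outing's fixes to home. When a
#' boundary fix lies inside the home geofence (`home_radius_m`), the segment
#' from the home centroid to it is included -- the journey starts and ends at
#' home, and the fixes inside the geofence belong to the preceding or
#' following at-home dwell.
#'
#' @param outing_fixes Fix tibble with `lat`, `lon` and `mode`.
#' @param home c(lat, lon).
#' @param home_radius_m Geofence radius used for the home anchoring (0
#'   disables it).
#' @return Named list: `total_m`, `walking_m`, `mean_from_home_m`.
#' @export
outing_distances <- function(outing_fixes, home, home_radius_m = 30) {
  n <- nrow(outing_fixes)
  if (n < 2)
    return(list(total_m = 0, walking_m = 0,
                mean_from_home_m = if (n == 1)
                  dist_to_home(outing_fixes, home) else NA_real_))
  d <- haversine_m(outing_fixes$lat[-n], outing_fixes$lon[-n],
                   outing_fixes$lat[-1], outing_fixes$lon[-1])
  foot <- !is.na(outing_fixes$mode) & outing_fixes$mode == "by_foot"
  both_foot <- foot[-n] & foot[-1]
  total <- sum(d)
  walking <- sum(d[both_foot])
  dh <- dist_to_home(outing_fixes[c(1, n), ], home)
  for (side in 1:2) {
    idx <- if (side == 1) 1L else n
    nb <- if (side == 1) min(2L, n) else max(n - 1L, 1L)
    if (dh[side] <= home_radius_m) {
      total <- total + dh[side]
      if (foot[idx] && foot[nb]) walking <- walking + dh[side]
    }
  }
  list(total_m = total,
       walking_m = walking,
       mean_from_home_m = mean(dist_to_home(outing_fixes, home)))
}

#' Discrete Frechet distance between two trajectories
#'
#' The standard dynamic program over the coupling table
#' `c(i,j) = max(d(a_i, b_j), min(c(i-1,j), c(i-1,j-1), c(i,j-1)))`,
#' returning `c(n,m)`: the smallest over all monotone couplings of the
#' maximum coupled point-pair distance. With `units = "meters"` point
#' distances are geodesic (haversine); with `"degrees"` they are Euclidean in
#' raw coordinate space (for comparability with analyses that skipped
#' projection).
#'
#' @param a,b Matrices or data frames with `lat`, `lon` columns (or two
#'   unnamed columns in that order), at least one row each.
#' @param units `"meters"` or `"degrees"`.
#' @return The discrete Frechet distance (scalar).
#' @export
discrete_frechet <- function(a, b, units = c("meters", "degrees")) {
  units <- match.arg(units)
  a <- traj_matrix(a); b <- traj_matrix(b)
  if (nrow(a) < 1 || nrow(b) < 1) stop("empty trajectory", call. = FALSE)
  dfd_cpp(a, b, if (units == "meters") 0L else 1L)
}

traj_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (all(c("lat", "lon") %in% names(x))) x <- cbind(x$lat, x$lon)
    else x <- as.matrix(x[, 1:2])
  }
  storage.mode(x) <- "double"
  x
}

downsample_traj <- function(m, max_points) {
  n <- nrow(m)
  if (n <= max_points) return(m)
  m[unique(round(seq(1, n, length.out = max_points))), , drop = FALSE]
}

#' Mean pairwise trajectory similarity of a participant's outings
#'
#' Computes the discrete Frechet distance for every unordered pair of outing
#' trajectories (self-pairs excluded) and returns the mean. Trajectories are
#' first downsampled by uniform stride to at most `max_points` fixes to bound
#' the quadratic coupling table.
#'
#' @param outings Outing tibble with a `fixes` list column (or a plain list
#'   of fix tibbles).
#' @param units See [discrete_frechet()].
#' @param max_points Downsampling bound.
#' @return Mean pairwise distance, or `NA` with fewer than 2 outings.
#' @export
trajectory_similarity <- function(outings, units = c("meters", "degrees"),
                                  max_points = 500) {
  units <- match.arg(units)
  trajs <- if (is.data.frame(outings)) outings$fixes else outings
  k <- length(trajs)
  if (k < 2) {
    gm_log("debug", "fewer than 2 outings: trajectory similarity undefined")
    return(NA_real_)
  }
  mats <- lapply(trajs, function(f) downsample_traj(traj_matrix(f), max_points))
  if (units == "meters") {
    # shared local projection, then Euclidean point distances: equal to the
    # geodesic computation to within ~1e-6 relative at outing scales, and an
    # order of magnitude faster over all O(k^2) pairs
    ctr <- colMeans(do.call(rbind, mats))
    mats <- lapply(mats, function(m)
      aeq_project(m[, 1], m[, 2], ctr[1], ctr[2]))
  }
  vals <- numeric(0)
  for (i in seq_len(k - 1))
    for (j in seq((i + 1), k))
      vals <- c(vals, dfd_cpp(mats[[i]], mats[[j]], 1L))
  mean(vals)
}

#' Compute the eight-variable mobility profile
#'
#' @param outings Outing tibble (with `band`, `fixes`, `mode`-annotated
#'   fixes).
#' @param recorded_days Days surviving [clean_days()].
#' @param home c(lat, lon).
#' @param interval_s Sampling interval, s.
#' @param config A [pipeline_config()] (for the Frechet settings).
#' @return One-row tibble with the eight variables plus `n_outings` and
#'   `recorded_days`. With zero outings the rate variables are 0 and the
#'   per-outing variables `NA`.
#' @export
compute_profile <- function(outings, recorded_days, home, interval_s,
                            config = pipeline_config()) {
  k <- nrow(outings)
  rates <- outing_rates(outings, recorded_days)
  if (k == 0) {
    per <- list(moving_hours_per_outing = NA_real_,
                total_km_per_outing = NA_real_,
                walking_km_per_outing = NA_real_,
                mean_km_from_home_per_outing = NA_real_)
    dfd <- NA_real_
  } else {
    mv <- vapply(outings$fixes, moving_time, 0, interval_s = interval_s)
    dd <- lapply(outings$fixes, outing_distances, home = home)
    per <- list(
      moving_hours_per_outing = mean(mv),
      total_km_per_outing = mean(vapply(dd, `[[`, 0, "total_m")) / 1000,
      walking_km_per_outing = mean(vapply(dd, `[[`, 0, "walking_m")) / 1000,
      mean_km_from_home_per_outing =
        mean(vapply(dd, `[[`, 0, "mean_from_home_m")) / 1000)
    dfd <- trajectory_similarity(outings, units = config$dfd_units,
                                 max_points = config$dfd_max_points)
  }
  tibble::tibble(
    outings_per_day = rates$total,
    day_outings_per_day = rates$day,
    night_outings_per_day = rates$night,
    moving_hours_per_outing = per$moving_hours_per_outing,
    total_km_per_outing = per$total_km_per_outing,
    walking_km_per_outing = per$walking_km_per_outing,
    mean_km_from_home_per_outing = per$mean_km_from_home_per_outing,
    mean_dfd = dfd,
    n_outings = k,
    recorded_days = recorded_days)
}
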