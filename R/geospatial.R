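## Buffer-zone extraction of environmental features around walking
## trajectories. Geometry is computed in a local azimuthal-equidistant frame
## centred on the trajectory; the buffer polygon is the Minkowski dilation of
## the polyline, represented exactly as the union of per-segment rectangles
## and per-vertex discs.

#' Build a buffer zone around a trajectory
#'
#' @param traj Data frame/matrix with `lat`, `lon` (NA rows separate disjoint
#'   polyline parts), at least one finite point.
#' @param radius_m Buffer radius, m (> 0).
#' @return A `buffer_zone`: projected polyline, radius and projection centre.
#' @export
build_buffer <- function(traj, radius_m) {
  if (radius_m <= 0) stop("radius must be > 0", call. = FALSE)
  m <- traj_matrix(traj)
  fin <- is.finite(m[, 1])
  if (!any(fin)) stop("trajectory has no finite points", call. = FALSE)
  lat0 <- mean(m[fin, 1]); lon0 <- mean(m[fin, 2])
  xy <- matrix(NA_real_, nrow(m), 2)
  xy[fin, ] <- aeq_project(m[fin, 1], m[fin, 2], lat0, lon0)
  structure(list(xy = xy, radius_m = radius_m, lat0 = lat0, lon0 = lon0),
            class = "buffer_zone")
}

#' @export
print.buffer_zone <- function(x, ...) {
  cat(sprintf("<buffer_zone> radius %g m around %d-vertex polyline\n",
              x$radius_m, sum(is.finite(x$xy[, 1]))))
  invisible(x)
}

#' Test points for buffer membership
#'
#' @param buffer A [build_buffer()] object.
#' @param lat,lon Point coordinates, degrees.
#' @return Logical vector.
#' @export
buffer_contains <- function(buffer, lat, lon) {
  if (!length(lat)) return(logical())
  p <- aeq_project(lat, lon, buffer$lat0, buffer$lon0)
  pts_in_buffer_cpp(p[, 1], p[, 2], buffer$xy[, 1], buffer$xy[, 2],
                    buffer$radius_m)
}

#' Buffer polygon area by midpoint grid integration
#'
#' @param buffer A `buffer_zone`.
#' @param cell_m Grid cell size; the default (radius / 150) keeps the
#'   integration error well under 0.5% for the shapes used here.
#' @return Area in square meters.
#' @export
buffer_area <- function(buffer, cell_m = buffer$radius_m / 150) {
  xy <- buffer$xy[is.finite(buffer$xy[, 1]), , drop = FALSE]
  r <- buffer$radius_m
  gx <- seq(min(xy[, 1]) - r, max(xy[, 1]) + r, by = cell_m)
  gy <- seq(min(xy[, 2]) - r, max(xy[, 2]) + r, by = cell_m)
  gx <- gx + cell_m / 2; gy <- gy + cell_m / 2
  g <- expand.grid(x = gx, y = gy)
  inside <- pts_in_buffer_cpp(g$x, g$y, buffer$xy[, 1], buffer$xy[, 2], r)
  sum(inside) * cell_m^2
}

#' Export a buffer zone to GeoJSON for inspection
#'
#' Writes the buffer's constituent primitives (vertex discs polygonised to
#' 64-gons, segment rectangles) as a MultiPolygon-per-feature collection.
#'
#' @param buffer A `buffer_zone`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_buffer_geojson <- function(buffer, path) {
  xy <- buffer$xy
  r <- buffer$radius_m
  ring_ll <- function(px, py) {
    ll <- aeq_unproject(px, py, buffer$lat0, buffer$lon0)
    lapply(seq_len(nrow(ll)), function(i) c(ll[i, "lon"], ll[i, "lat"]))
  }
  polys <- list()
  th <- seq(0, 2 * pi, length.out = 65)
  for (i in seq_len(nrow(xy))) {
    if (!is.finite(xy[i, 1])) next
    polys[[length(polys) + 1L]] <-
      list(ring_ll(xy[i, 1] + r * cos(th), xy[i, 2] + r * sin(th)))
    if (i < nrow(xy) && is.finite(xy[i + 1, 1])) {
      sx <- xy[i + 1, 1] - xy[i, 1]; sy <- xy[i + 1, 2] - xy[i, 2]
      len <- sqrt(sx^2 + sy^2)
      if (len > 0) {
        ux <- -sy / len * r; uy <- sx / len * r
        px <- c(xy[i, 1] + ux, xy[i + 1, 1] + ux, xy[i + 1, 1] - ux,
                xy[i, 1] - ux, xy[i, 1] + ux)
        py <- c(xy[i, 2] + uy, xy[i + 1, 2] + uy, xy[i + 1, 2] - uy,
                xy[i, 2] - uy, xy[i, 2] + uy)
        polys[[length(polys) + 1L]] <- list(ring_ll(px, py))
      }
    }
  }
  feat <- list(type = "Feature",
               properties = list(radius_m = r),
               geometry = list(type = "MultiPolygon", coordinates = polys))
  jsonlite::write_json(list(type = "FeatureCollection", features = list(feat)),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Landmark density within a buffer
#'
#' @param buffer A `buffer_zone`.
#' @param landmarks Tibble with `lat`, `lon`.
#' @param walking_km Total walking distance used for normalisation (> 0).
#' @return Landmarks per walking km (`NA` when `walking_km` is 0).
#' @export
landmark_density <- function(buffer, landmarks, walking_km) {
  if (is.na(walking_km) || walking_km <= 0) return(NA_real_)
  sum(buffer_contains(buffer, landmarks$lat, landmarks$lon)) / walking_km
}

#' Road-intersection density and mean complexity within a buffer
#'
#' Intersections are road-network nodes of degree >= 3; complexity is the
#' node degree (number of road legs).
#'
#' @param buffer A `buffer_zone` (30 m road buffer).
#' @param env An [environment_layer()].
#' @param walking_km Normalisation distance (> 0).
#' @return Named list: `intersection_density` (per walking km),
#'   `mean_complexity` (`NA` when no intersection falls in the buffer).
#' @export
intersection_stats <- function(buffer, env, walking_km) {
  if (is.na(walking_km) || walking_km <= 0)
    return(list(intersection_density = NA_real_, mean_complexity = NA_real_))
  deg <- node_degree(env)
  inter <- env$nodes[deg[env$nodes$id] >= 3, , drop = FALSE]
  if (nrow(inter) == 0)
    return(list(intersection_density = 0, mean_complexity = NA_real_))
  inside <- buffer_contains(buffer, inter$lat, inter$lon)
  if (!any(inside))
    return(list(intersection_density = 0, mean_complexity = NA_real_))
  list(intersection_density = sum(inside) / walking_km,
       mean_complexity = mean(deg[inter$id[inside]]))
}

#' Street orientation entropy within a buffer
#'
#' Every road edge is subdivided into sub-segments of at most `step_m`;
#' sub-segments whose midpoints fall inside the buffer contribute their
#' length to the angular bin of their compass bearing and of its reverse
#' (streets are undirected). Bins are centred on multiples of the bin width.
#' The result is the Shannon entropy of the length-weighted bin distribution,
#' in nats: 0 for a single straight street direction pair is ln 2, an
#' orthogonal grid gives ln 4, and a uniform bearing spread gives ln(bins).
#'
#' @param buffer A `buffer_zone` (2.03 km entropy buffer).
#' @param env An [environment_layer()].
#' @param bins Number of angular bins over 0-360 degrees.
#' @param step_m Clipping sub-segment length.
#' @return Entropy in nats, in 0..ln(bins); `NA` when no road falls in the
#'   buffer.
#' @export
orientation_entropy <- function(buffer, env, bins = 36, step_m = 10) {
  if (nrow(env$edges) == 0) return(NA_real_)
  node_xy <- aeq_project(env$nodes$lat, env$nodes$lon, buffer$lat0,
                         buffer$lon0)
  rownames(node_xy) <- env$nodes$id
  width <- 360 / bins
  wt <- numeric(bins)
  for (i in seq_len(nrow(env$edges))) {
    a <- node_xy[env$edges$from[i], ]; b <- node_xy[env$edges$to[i], ]
    dx <- b[1] - a[1]; dy <- b[2] - a[2]
    len <- sqrt(dx^2 + dy^2)
    if (len == 0) next
    ns <- max(1L, ceiling(len / step_m))
    tm <- (seq_len(ns) - 0.5) / ns
    mx <- a[1] + tm * dx; my <- a[2] + tm * dy
    inside <- pts_in_buffer_cpp(mx, my, buffer$xy[, 1], buffer$xy[, 2],
                                buffer$radius_m)
    l_in <- sum(inside) * len / ns
    if (l_in == 0) next
    br <- bearing_deg(dx, dy)
    for (bng in c(br, (br + 180) %% 360)) {
      bin <- floor(((bng + width / 2) %% 360) / width) + 1L
      wt[bin] <- wt[bin] + l_in
    }
  }
  tot <- sum(wt)
  if (tot == 0) return(NA_real_)
  p <- wt[wt > 0] / tot
  -sum(p * log(p))
}

#' Assemble a participant's walking trajectory
#'
#' Concatenates the runs of consecutive by-foot fixes across all outings into
#' one NA-separated polyline, optionally thinned to a minimum vertex spacing.
#'
#' @param outings Outing tibble with `mode`-annotated `fixes`.
#' @param simplify_m Minimum vertex spacing (0 keeps every fix).
#' @return Tibble with `lat`, `lon` (NA rows separate parts); zero rows when
#'   no walking fixes exist.
#' @export
walking_trajectory <- function(outings, simplify_m = 0) {
  parts <- list()
  for (f in outings$fixes) {
    foot <- !is.na(f$mode) & f$mode == "by_foot"
    if (!any(foot)) next
    r <- rle(foot)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      seg <- f[starts[j]:ends[j], c("lat", "lon")]
      if (simplify_m > 0 && nrow(seg) > 2) {
        d <- c(0, cumsum(haversine_m(seg$lat[-nrow(seg)], seg$lon[-nrow(seg)],
                                     seg$lat[-1], seg$lon[-1])))
        keep <- !duplicated(floor(d / simplify_m))
        keep[nrow(seg)] <- TRUE
        seg <- seg[keep, , drop = FALSE]
      }
      parts[[length(parts) + 1L]] <- seg
    }
  }
  if (!length(parts)) return(tibble::tibble(lat = numeric(), lon = numeric()))
  na_row <- tibble::tibble(lat = NA_real_, lon = NA_real_)
  dplyr::bind_rows(purrr::map(parts, ~ dplyr::bind_rows(.x, na_row)))
}

#' Geospatial feature set of one participant
#'
#' Builds the 80 m landmark, 30 m road and 2.03 km entropy buffers around the
#' participant's walking trajectories and extracts landmark density,
#' intersection density/complexity and orientation entropy.
#'
#' @param outings Outing tibble with `mode`-annotated fixes.
#' @param env An [environment_layer()].
#' @param config A [pipeline_config()].
#' @return One-row tibble of the four features plus `walking_km`.
#' @export
geo_features <- function(outings, env, config = pipeline_config()) {
  na_row <- tibble::tibble(landmark_density = NA_real_,
                           intersection_density = NA_real_,
                           mean_intersection_complexity = NA_real_,
                           orientation_entropy = NA_real_,
                           walking_km = NA_real_)
  if (nrow(outings) == 0) return(na_row)
  traj <- walking_trajectory(outings, simplify_m = config$buffer_simplify_m)
  if (!nrow(traj)) return(na_row)
  dd <- lapply(outings$fixes, outing_distances,
               home = c(traj$lat[1], traj$lon[1]))
  walking_km <- sum(vapply(dd, `[[`, 0, "walking_m")) / 1000
  if (walking_km <= 0) return(na_row)
  buf_lm <- build_buffer(traj, config$landmark_core_radius_m +
                           config$error_buffer_m)
  buf_rd <- build_buffer(traj, config$road_radius_m)
  traj_coarse <- thin_na_polyline(traj, 50)
  buf_en <- build_buffer(traj_coarse, config$entropy_core_radius_m +
                           config$error_buffer_m)
  is_ <- intersection_stats(buf_rd, env, walking_km)
  tibble::tibble(
    landmark_density = landmark_density(buf_lm, env$landmarks, walking_km),
    intersection_density = is_$intersection_density,
    mean_intersection_complexity = is_$mean_complexity,
    orientation_entropy = orientation_entropy(buf_en, env,
                                              bins = config$entropy_bins,
                                              step_m = config$entropy_step_m),
    walking_km = walking_km)
}

## thin an NA-separated polyline to ~spacing_m vertex spacing (the entropy
## buffer radius dwarfs the removed detail)
thin_na_polyline <- function(traj, spacing_m) {
  fin <- is.finite(traj$lat)
  part <- cumsum(!fin)[fin]
  sub <- traj[fin, , drop = FALSE]
  keep <- logical(nrow(sub))
  for (p in unique(part)) {
    idx <- which(part == p)
    seg <- sub[idx, ]
    if (nrow(seg) <= 2) { keep[idx] <- TRUE; next }
    d <- c(0, cumsum(haversine_m(seg$lat[-nrow(seg)], seg$lon[-nrow(seg)],
                                 seg$lat[-1], seg$lon[-1])))
    k <- !duplicated(floor(d / spacing_m))
    k[c(1, nrow(seg))] <- TRUE
    keep[idx] <- k
  }
  out <- sub[keep, , drop = FALSE]
  na_row <- tibble::tibble(lat = NA_real_, lon = NA_real_)
  res <- list()
  for (p in unique(part[keep])) {
    res[[length(res) + 1L]] <- out[part[keep] == p, , drop = FALSE]
    res[[length(res) + 1L]] <- na_row
  }
  dplyr::bind_rows(res)
}
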