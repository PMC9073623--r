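# Independent oracles and small fixture builders used across the suite.

# Brute-force discrete Frechet distance: enumerate all monotone couplings
# (steps advance one or both sequences) and take the min over couplings of
# the max coupled pair distance. Exponential -- only for tiny inputs.
dfd_brute <- function(a, b, dist_fun) {
  n <- nrow(a); m <- nrow(b)
  d <- outer(seq_len(n), seq_len(m),
             Vectorize(function(i, j) dist_fun(a[i, ], b[j, ])))
  best <- Inf
  rec <- function(i, j, cur) {
    cur <- max(cur, d[i, j])
    if (cur >= best) return(invisible())
    if (i == n && j == m) { best <<- cur; return(invisible()) }
    if (i < n) rec(i + 1L, j, cur)
    if (j < m) rec(i, j + 1L, cur)
    if (i < n && j < m) rec(i + 1L, j + 1L, cur)
    invisible()
  }
  rec(1L, 1L, 0)
  best
}

hav_oracle <- function(p, q) {
  # plain-R haversine, independent of the package's compiled path
  rad <- pi / 180
  dlat <- (q[1] - p[1]) * rad / 2
  dlon <- (q[2] - p[2]) * rad / 2
  a <- sin(dlat)^2 + cos(p[1] * rad) * cos(q[1] * rad) * sin(dlon)^2
  2 * 6371008.8 * asin(sqrt(pmin(a, 1)))
}

# distance from point (px, py) to segment (ax, ay)-(bx, by), planar
pt_seg_dist <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  l2 <- vx^2 + vy^2
  if (l2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- max(0, min(1, ((px - ax) * vx + (py - ay) * vy) / l2))
  sqrt((px - ax - t * vx)^2 + (py - ay - t * vy)^2)
}

# oracle membership: min distance from point to NA-separated polyline <= r
in_buffer_oracle <- function(px, py, lx, ly, r) {
  dmin <- Inf
  for (j in seq_along(lx)) {
    if (is.na(lx[j])) next
    if (j < length(lx) && !is.na(lx[j + 1])) {
      dmin <- min(dmin, pt_seg_dist(px, py, lx[j], ly[j],
                                    lx[j + 1], ly[j + 1]))
    } else {
      dmin <- min(dmin, sqrt((px - lx[j])^2 + (py - ly[j])^2))
    }
  }
  dmin <= r
}

# build a gps_trace from local-meter offsets around a home point
HOME <- c(52.628, 1.299)

trace_from_xy <- function(x, y, t0 = as.POSIXct("2023-05-01 10:00:00",
                                                tz = "UTC"),
                          interval_s = 3, speed_kmh = NULL,
                          participant_id = "T01") {
  ll <- aeq_unproject(x, y, HOME[1], HOME[2])
  fixes <- tibble::tibble(
    timestamp = t0 + seq_along(x) * interval_s - interval_s,
    lat = ll[, "lat"], lon = ll[, "lon"])
  if (!is.null(speed_kmh)) fixes$speed_kmh <- speed_kmh
  gps_trace(participant_id, fixes, interval_s = interval_s)
}

# straight out-and-back walking trace: out `dist_m` east and back, constant
# speed, fixes every interval
walk_out_and_back <- function(dist_m, speed_kmh = 4.5, interval_s = 3, ...) {
  step <- speed_kmh / 3.6 * interval_s
  out <- seq(0, dist_m, by = step)
  x <- c(out, rev(out[-length(out)]))
  trace_from_xy(x, rep(0, length(x)), interval_s = interval_s,
                speed_kmh = speed_kmh, ...)
}

rand_traj <- function(n, scale_deg = 0.01) {
  cbind(52.6 + cumsum(rnorm(n, 0, scale_deg)),
        1.3 + cumsum(rnorm(n, 0, scale_deg)))
}

dist_to_home_test <- function(row) {
  hav_oracle(c(row$lat, row$lon), HOME)
}
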