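## Synthetic cohort generator with planted ground truth. Every quantity the
## pipeline later estimates (outing counts/bands, per-fix transport modes,
## path lengths, moving durations, spike indices) is recorded at generation
## time, so the generator doubles as the validation oracle for the analysis.

#' Per-condition outing parameters
#'
#' One block of outing-process parameters: Poisson rates per tracked day in
#' the daytime and nighttime bands, and the per-outing distance mixture (a
#' lognormal walking component plus, with probability `p_vehicle`, a lognormal
#' vehicle component).
#'
#' @param rate_day,rate_night Mean outings per day started in each band.
#' @param walk_km_mean,walk_km_sd Per-outing walking distance (km).
#' @param p_vehicle Probability an outing includes a vehicle trip.
#' @param vehicle_km_mean,vehicle_km_sd Per-outing vehicle distance (km).
#' @return A `cond_params` list.
#' @export
cond_params <- function(rate_day, rate_night, walk_km_mean, walk_km_sd,
                        p_vehicle, vehicle_km_mean, vehicle_km_sd) {
  stopifnot(rate_day >= 0, rate_night >= 0, walk_km_mean > 0,
            p_vehicle >= 0, p_vehicle <= 1)
  structure(list(rate_day = rate_day, rate_night = rate_night,
                 walk_km_mean = walk_km_mean, walk_km_sd = walk_km_sd,
                 p_vehicle = p_vehicle, vehicle_km_mean = vehicle_km_mean,
                 vehicle_km_sd = vehicle_km_sd),
            class = "cond_params")
}

default_conditions <- function() {
  list(
    control = list(
      all = cond_params(1.89, 0.38, 1.94, 1.00, 0.75, 28.6, 17.0)),
    patient = list(
      accompanied = cond_params(1.36, 0.21, 1.33, 0.91, 0.60, 27.2, 16.0),
      alone = cond_params(1.02, 0.01, 0.94, 1.14, 0.35, 10.4, 8.0)))
}

#' Cohort generation specification
#'
#' Defaults describe the emulated study: 18 controls and 15 patients tracked
#' for 14 days at 3 s or 5 s sampling, 10 m GPS error SD, recording gaps after
#' 2 min without movement, and per-condition outing rates and distances on the
#' scale of the cohorts this pipeline targets (controls / patients accompanied
#' / patients alone). GPS error is a first-order autoregressive (Gauss-Markov)
#' process per axis with marginal SD `gps_sigma_m` and correlation time
#' `noise_tau_s`, restarted at every recording gap: receiver error is strongly
#' correlated over seconds-to-minutes, and modelling it as white noise per fix
#' would inflate recovered path lengths several-fold at walking speeds.
#'
#' @param n_control,n_patient Group sizes.
#' @param tracking_days Days of tracking per participant.
#' @param conditions Nested list group -> condition -> [cond_params()].
#' @param gps_sigma_m Marginal position error SD in meters.
#' @param noise_tau_s Correlation time of the error process, seconds.
#' @param spike_rate_per_1000 Expected spikes per 1000 fixes. Spikes displace
#'   single non-vehicle, non-gap-leading fixes (displacements on vehicle fixes
#'   at 5 s sampling can be kinematically plausible, and a displacement on the
#'   first fix after a gap is indistinguishable from real movement).
#' @param spike_min_m,spike_max_m Spike displacement range, meters.
#' @param walk_speed_mean_kmh,walk_speed_sd_kmh Per-outing walking speed,
#'   normal truncated > 0.5 km/h.
#' @param vehicle_speed_mean_kmh,vehicle_speed_sd_kmh,vehicle_speed_min_kmh
#'   Per-outing vehicle speed, normal truncated at the minimum.
#' @param stop_prob Probability of a mid-outing stop at the far point.
#' @param stop_min_s,stop_max_s Stop duration range (recording resumes on
#'   movement; only the first `gap_s` seconds of a stop are recorded).
#' @param rate_factor_cv,dist_factor_cv Coefficient of variation of the
#'   per-participant gamma random factors multiplying rates and distances
#'   (the source of between-participant spread).
#' @param walk_km_min,vehicle_km_min Lower truncation of drawn distances.
#' @param stroll_rate_per_day Rate of sub-100 m out-and-back strolls (beyond
#'   the 30 m geofence but below the outing path threshold).
#' @param p_disorient Probability a patient is flagged as having experienced
#'   spatial disorientation during tracking.
#' @param frac_interval3 Named vector: fraction of each group sampled at 3 s
#'   (the rest at 5 s).
#' @param home_recording_s Seconds of at-home fixes recorded after returning
#'   (in-home activity keeps the device awake for a while).
#' @param heartbeat One daily at-home recording block at 03:00 local so that
#'   every day has some data even without outings.
#' @param diary_omission Probability a patient outing is missing from the
#'   diary.
#' @param diary_jitter_sd_min SD (minutes) of diary start-time error.
#' @param n_routes Habitual routes per participant; outings reuse them.
#' @param waypoint_spacing_m,heading_jitter_deg Route geometry controls.
#' @param start_date First tracking day (local).
#' @param tz Time zone of the cohort.
#' @param env_kind,extent_m,landmark_count Environment layer controls
#'   (see [generate_environment()]).
#' @param fixed_daily_outings Optional integer vector: exact outings per day
#'   (recycled over days, applied to each condition) replacing the Poisson
#'   draw; bands are then assigned by the band-rate proportions.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_control = 18, n_patient = 15, tracking_days = 14,
                        conditions = default_conditions(),
                        gps_sigma_m = 10, noise_tau_s = 300,
                        spike_rate_per_1000 = 1,
                        spike_min_m = 300, spike_max_m = 1000,
                        walk_speed_mean_kmh = 4.5, walk_speed_sd_kmh = 1.0,
                        vehicle_speed_mean_kmh = 40, vehicle_speed_sd_kmh = 10,
                        vehicle_speed_min_kmh = 15,
                        stop_prob = 0.3, stop_min_s = 300, stop_max_s = 900,
                        rate_factor_cv = 0.35, dist_factor_cv = 0.45,
                        walk_km_min = 0.25, vehicle_km_min = 1,
                        stroll_rate_per_day = 0.2,
                        p_disorient = 0.4,
                        frac_interval3 = c(control = 13 / 18, patient = 9 / 15),
                        home_recording_s = 120, heartbeat = TRUE,
                        diary_omission = 0, diary_jitter_sd_min = 5,
                        n_routes = 5, waypoint_spacing_m = 100,
                        heading_jitter_deg = 8,
                        start_date = "2023-05-01", tz = "Europe/London",
                        env_kind = "irregular", extent_m = 3000,
                        landmark_count = 120,
                        fixed_daily_outings = NULL) {
  spec <- as.list(environment())
  stopifnot(tracking_days >= 1, gps_sigma_m >= 0, spike_rate_per_1000 >= 0,
            stroll_rate_per_day >= 0, p_disorient >= 0, p_disorient <= 1,
            diary_omission >= 0, diary_omission <= 1)
  for (grp in spec$conditions)
    for (cp in grp) stopifnot(inherits(cp, "cond_params"))
  structure(spec, class = "cohort_spec")
}

## lognormal draw with given mean/sd on the natural scale
rlnorm_ms <- function(n, m, s, min = 0) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  pmax(rlnorm(n, meanlog, sdlog), min)
}

rnorm_trunc <- function(n, m, s, min) {
  x <- rnorm(n, m, s)
  while (any(bad <- x <= min)) x[bad] <- rnorm(sum(bad), m, s)
  x
}

#' Generate a synthetic environment layer
#'
#' `grid` is an orthogonal street grid (two orientations); `irregular` a
#' jittered grid (varied orientations); `single_street` one straight segment;
#' `star` 36 equal segments radiating at 10 degree spacing. Landmarks are
#' placed uniformly at random in the square extent.
#'
#' @param kind One of `"grid"`, `"irregular"`, `"single_street"`, `"star"`.
#' @param extent_m Side of the square extent (m); the network spans it.
#' @param landmark_count Number of landmark points.
#' @param seed Integer seed.
#' @param center c(lat, lon) of the extent centre.
#' @param spacing_m Street spacing for grid/irregular.
#' @return An [environment_layer()].
#' @export
generate_environment <- function(kind = c("grid", "irregular", "single_street",
                                          "star"),
                                 extent_m = 3000, landmark_count = 100,
                                 seed = 1L,
                                 center = c(lat = 52.628, lon = 1.299),
                                 spacing_m = 200) {
  kind <- match.arg(kind)
  stopifnot(extent_m > 0, landmark_count >= 0)
  set.seed(seed)
  half <- extent_m / 2
  if (kind %in% c("grid", "irregular")) {
    k <- max(2L, floor(extent_m / spacing_m) + 1L)
    gx <- seq(-half, half, length.out = k)
    nodes_xy <- expand.grid(ix = seq_len(k), iy = seq_len(k))
    nodes_xy$x <- gx[nodes_xy$ix]; nodes_xy$y <- gx[nodes_xy$iy]
    if (kind == "irregular") {
      jit <- spacing_m * 0.35
      nodes_xy$x <- nodes_xy$x + runif(nrow(nodes_xy), -jit, jit)
      nodes_xy$y <- nodes_xy$y + runif(nrow(nodes_xy), -jit, jit)
    }
    id_of <- function(ix, iy) paste0("n", ix, "_", iy)
    nodes_xy$id <- id_of(nodes_xy$ix, nodes_xy$iy)
    eh <- with(subset(nodes_xy, ix < k),
               data.frame(from = id_of(ix, iy), to = id_of(ix + 1L, iy)))
    ev <- with(subset(nodes_xy, iy < k),
               data.frame(from = id_of(ix, iy), to = id_of(ix, iy + 1L)))
    edges <- rbind(eh, ev)
    nodes <- nodes_xy[c("id", "x", "y")]
  } else if (kind == "single_street") {
    nodes <- data.frame(id = c("a", "b"), x = c(-half, half), y = c(0, 0))
    edges <- data.frame(from = "a", to = "b")
  } else { # star
    ang <- (0:35) * 10 * pi / 180
    nodes <- data.frame(id = c("c", paste0("s", 0:35)),
                        x = c(0, half * sin(ang)),
                        y = c(0, half * cos(ang)))
    edges <- data.frame(from = "c", to = paste0("s", 0:35))
  }
  ll <- aeq_unproject(nodes$x, nodes$y, center[["lat"]], center[["lon"]])
  node_df <- tibble::tibble(id = nodes$id, lat = ll[, "lat"], lon = ll[, "lon"])
  lm_xy <- matrix(runif(2 * landmark_count, -half, half), ncol = 2)
  lm_ll <- aeq_unproject(lm_xy[, 1], lm_xy[, 2], center[["lat"]],
                         center[["lon"]])
  landmarks <- tibble::tibble(lat = lm_ll[, "lat"], lon = lm_ll[, "lon"])
  environment_layer(landmarks, node_df, tibble::as_tibble(edges),
                    center = c(center[["lat"]], center[["lon"]]))
}

## Synthesize one outing's noise-free fixes in meters relative to home.
## Returns list(t, x, y, mode, speed_kmh, truth row fields).
synth_outing <- function(walk_km, vehicle_km, v_walk_kmh, v_vehicle_kmh,
                         bearing_deg0, interval_s, stop_s, gap_s,
                         waypoint_spacing_m, heading_jitter_deg) {
  W <- walk_km * 1000; V <- vehicle_km * 1000
  vw <- v_walk_kmh / 3.6; vv <- v_vehicle_kmh / 3.6
  d_out <- (W + V) / 2
  n_wp <- max(1L, ceiling(d_out / waypoint_spacing_m))
  steps <- rep(waypoint_spacing_m, n_wp)
  steps[n_wp] <- d_out - (n_wp - 1L) * waypoint_spacing_m
  dh <- cumsum(rnorm(n_wp, 0, heading_jitter_deg))
  dh <- pmin(pmax(dh, -25), 25)
  head_rad <- (bearing_deg0 + dh) * pi / 180
  wx <- c(0, cumsum(steps * sin(head_rad)))
  wy <- c(0, cumsum(steps * cos(head_rad)))
  s_wp <- c(0, cumsum(steps))
  # motion profile (time, cumulative distance along out-and-back path)
  t_w <- (W / 2) / vw
  t_v <- if (V > 0) (V / 2) / vv else 0
  bp_t <- c(0, t_w, t_w + t_v)
  bp_s <- c(0, W / 2, d_out)
  stop_start <- t_w + t_v
  if (stop_s > 0) { bp_t <- c(bp_t, stop_start + stop_s); bp_s <- c(bp_s, d_out) }
  t0_back <- bp_t[length(bp_t)]
  bp_t <- c(bp_t, t0_back + t_v, t0_back + t_v + t_w)
  bp_s <- c(bp_s, d_out + V / 2, 2 * d_out)
  total_t <- bp_t[length(bp_t)]
  dup <- duplicated(bp_t)
  t <- seq(0, total_t, by = interval_s)
  s <- stats::approx(bp_t[!dup], bp_s[!dup], t, rule = 2,
                     ties = "ordered")$y
  s_fold <- ifelse(s > d_out, 2 * d_out - s, s)
  dupw <- duplicated(s_wp)
  x <- stats::approx(s_wp[!dupw], wx[!dupw], s_fold, rule = 2,
                     ties = "ordered")$y
  y <- stats::approx(s_wp[!dupw], wy[!dupw], s_fold, rule = 2,
                     ties = "ordered")$y
  in_stop <- stop_s > 0 & t >= stop_start & t < stop_start + stop_s
  in_walk <- (t < t_w) | (t > total_t - t_w)
  mode <- ifelse(in_stop, "stationary",
                 ifelse(in_walk, "by_foot", "in_vehicle"))
  mode[length(mode)] <- "stationary" # arrival fix
  speed <- ifelse(mode == "stationary", 0,
                  ifelse(mode == "by_foot", v_walk_kmh, v_vehicle_kmh))
  # device stops recording after gap_s without movement
  keep <- !(in_stop & (t - stop_start) > gap_s)
  list(t = t[keep], x = x[keep], y = y[keep], mode = mode[keep],
       speed = speed[keep],
       moving_h = (W / vw + V / vv) / 3600,
       duration_s = total_t)
}

band_of_start <- function(start, tz) {
  lt <- lubridate::with_tz(start, tz)
  mins <- lubridate::hour(lt) * 60 + lubridate::minute(lt)
  ifelse(mins >= 360 & mins <= 1080, "day", "night")
}

#' Generate one participant's trace, diary and ground truth
#'
#' Plants outings day by day (Poisson counts per band and condition), builds
#' noise-free out-and-back trajectories along the participant's habitual
#' routes, samples them at the device interval, applies recording gaps,
#' correlated GPS noise and spikes, and records everything planted.
#'
#' @param spec A [cohort_spec()].
#' @param group `"control"` or `"patient"`.
#' @param home c(lat, lon) of the home centroid.
#' @param interval_s Sampling interval, 3 or 5 s.
#' @param participant_id Identifier.
#' @param seed Integer seed.
#' @param env Optional [environment_layer()]; if given, the home must lie
#'   within 1.5 half-extents of its centre.
#' @return A list with `trace` ([gps_trace()]), `diary` (tibble) and `truth`.
#' @export
generate_participant <- function(spec, group, home, interval_s,
                                 participant_id, seed, env = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), group %in% names(spec$conditions))
  if (!is.null(env)) {
    xy <- aeq_project(home[1], home[2], env$center[1], env$center[2])
    if (max(abs(xy)) > 0.75 * spec$extent_m)
      stop("home outside environment extent", call. = FALSE)
  }
  set.seed(seed)
  tz <- spec$tz
  conds <- spec$conditions[[group]]
  rate_f <- rgamma(1, shape = 1 / spec$rate_factor_cv^2,
                   scale = spec$rate_factor_cv^2)
  dist_f <- rgamma(1, shape = 1 / spec$dist_factor_cv^2,
                   scale = spec$dist_factor_cv^2)
  routes <- runif(spec$n_routes, 0, 360)
  day0 <- lubridate::force_tz(lubridate::ymd(spec$start_date), tz)

  # --- outing plan ---------------------------------------------------------
  plan <- list()
  for (d in seq_len(spec$tracking_days)) {
    midnight <- day0 + lubridate::days(d - 1L)
    for (cn in names(conds)) {
      cp <- conds[[cn]]
      if (!is.null(spec$fixed_daily_outings)) {
        n_tot <- spec$fixed_daily_outings[((d - 1L) %%
          length(spec$fixed_daily_outings)) + 1L]
        p_day <- if (cp$rate_day + cp$rate_night > 0)
          cp$rate_day / (cp$rate_day + cp$rate_night) else 1
        n_day <- rbinom(1, n_tot, p_day)
        n_night <- n_tot - n_day
      } else {
        n_day <- rpois(1, cp$rate_day * rate_f)
        n_night <- rpois(1, cp$rate_night * rate_f)
      }
      # 3 min guard around the band edges: a start planted at the boundary is
      # ambiguous under geofence-based detection (the detected start lags the
      # true departure by the time to cross the home radius)
      offs <- runif(n_day, 6 * 3600 + 180, 18 * 3600 - 180)
      if (n_night > 0) {
        early_len <- 5.75 * 3600 # 00:10 - 05:55
        late_len <- 5.9 * 3600   # 18:04 - 23:58
        u <- runif(n_night, 0, early_len + late_len)
        offs <- c(offs, ifelse(u < early_len, 600 + u,
                               18.0667 * 3600 + (u - early_len)))
      }
      if (length(offs))
        plan[[length(plan) + 1L]] <- tibble::tibble(
          day = d, condition = cn, is_stroll = FALSE,
          start = midnight + offs)
    }
    n_str <- rpois(1, spec$stroll_rate_per_day)
    if (n_str > 0)
      plan[[length(plan) + 1L]] <- tibble::tibble(
        day = d, condition = names(conds)[1], is_stroll = TRUE,
        start = midnight + runif(n_str, 8 * 3600, 20 * 3600))
  }
  plan <- if (length(plan)) dplyr::arrange(dplyr::bind_rows(plan), start)
    else tibble::tibble(day = integer(), condition = character(),
                        is_stroll = logical(),
                        start = day0[integer(0)])

  # --- synthesize outings sequentially -------------------------------------
  fix_blocks <- list(); truth_rows <- list()
  prev_free <- day0 - lubridate::days(1)
  oid <- 0L
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    cp <- conds[[row$condition]]
    start <- row$start
    if (start < prev_free) start <- prev_free
    if (row$is_stroll) {
      walk_km <- runif(1, 0.070, 0.090)
      veh_km <- 0; stop_s <- 0
    } else {
      walk_km <- rlnorm_ms(1, cp$walk_km_mean * dist_f, cp$walk_km_sd,
                           spec$walk_km_min)
      veh_km <- if (runif(1) < cp$p_vehicle)
        rlnorm_ms(1, cp$vehicle_km_mean * dist_f, cp$vehicle_km_sd,
                  spec$vehicle_km_min) else 0
      stop_s <- if (runif(1) < spec$stop_prob)
        runif(1, spec$stop_min_s, spec$stop_max_s) else 0
    }
    v_w <- rnorm_trunc(1, spec$walk_speed_mean_kmh, spec$walk_speed_sd_kmh, 0.5)
    v_v <- rnorm_trunc(1, spec$vehicle_speed_mean_kmh,
                       spec$vehicle_speed_sd_kmh, spec$vehicle_speed_min_kmh)
    bearing <- if (row$is_stroll) runif(1, 0, 360)
      else routes[sample.int(spec$n_routes, 1)]
    o <- synth_outing(walk_km, veh_km, v_w, v_v, bearing, interval_s,
                      stop_s, 120, spec$waypoint_spacing_m,
                      spec$heading_jitter_deg)
    oid <- oid + 1L
    times <- start + o$t
    arrival <- start + o$duration_s
    # post-return at-home recording block
    hb_t <- seq(interval_s, spec$home_recording_s, by = interval_s)
    fix_blocks[[length(fix_blocks) + 1L]] <- tibble::tibble(
      timestamp = c(times, arrival + hb_t),
      x = c(o$x, rep(0, length(hb_t))),
      y = c(o$y, rep(0, length(hb_t))),
      mode = c(o$mode, rep("stationary", length(hb_t))),
      speed_kmh = c(o$speed, rep(0, length(hb_t))),
      outing_id = c(rep(oid, length(o$t)), rep(NA_integer_, length(hb_t))))
    truth_rows[[oid]] <- tibble::tibble(
      outing_id = oid, condition = row$condition, is_stroll = row$is_stroll,
      start = start, end = arrival,
      band = band_of_start(start, tz),
      walk_km = walk_km, vehicle_km = veh_km,
      path_km = walk_km + veh_km,
      moving_h = o$moving_h,
      mean_home_km = mean(sqrt(o$x^2 + o$y^2)) / 1000,
      n_fixes = length(o$t))
    prev_free <- arrival + spec$home_recording_s + runif(1, 180, 900)
  }
  truth_outings <- if (oid > 0) dplyr::bind_rows(truth_rows)
    else tibble::tibble(outing_id = integer(), condition = character(),
                        is_stroll = logical(), start = day0[integer(0)],
                        end = day0[integer(0)], band = character(),
                        walk_km = numeric(), vehicle_km = numeric(),
                        path_km = numeric(), moving_h = numeric(),
                        mean_home_km = numeric(), n_fixes = integer())

  # --- daily heartbeat blocks ----------------------------------------------
  if (spec$heartbeat) {
    for (d in seq_len(spec$tracking_days)) {
      hb <- day0 + lubridate::days(d - 1L) + 3 * 3600
      hb_end <- hb + spec$home_recording_s
      clash <- nrow(truth_outings) > 0 &&
        any(truth_outings$start - 1800 < hb_end &
            truth_outings$end + spec$home_recording_s + 600 > hb)
      if (!clash) {
        tt <- seq(0, spec$home_recording_s, by = interval_s)
        fix_blocks[[length(fix_blocks) + 1L]] <- tibble::tibble(
          timestamp = hb + tt, x = 0, y = 0, mode = "stationary",
          speed_kmh = 0, outing_id = NA_integer_)
      }
    }
  }

  fixes <- dplyr::arrange(dplyr::bind_rows(fix_blocks), .data$timestamp)
  fixes <- fixes[!duplicated(fixes$timestamp), , drop = FALSE]
  n <- nrow(fixes)

  # --- correlated GPS noise, restarted at each recording gap ---------------
  ex <- numeric(n); ey <- numeric(n)
  if (spec$gps_sigma_m > 0 && n > 0) {
    dt <- c(Inf, diff(as.numeric(fixes$timestamp)))
    new_block <- dt > 120
    phi <- exp(-interval_s / spec$noise_tau_s)
    innov <- spec$gps_sigma_m * sqrt(1 - phi^2)
    zx <- rnorm(n); zy <- rnorm(n)
    for (i in seq_len(n)) {
      if (new_block[i]) {
        ex[i] <- spec$gps_sigma_m * zx[i]; ey[i] <- spec$gps_sigma_m * zy[i]
      } else {
        ex[i] <- phi * ex[i - 1] + innov * zx[i]
        ey[i] <- phi * ey[i - 1] + innov * zy[i]
      }
    }
  }

  # --- spikes: single displaced fixes, unambiguous by construction ---------
  spike_idx <- integer(0)
  if (spec$spike_rate_per_1000 > 0 && n > 2) {
    dt <- c(Inf, diff(as.numeric(fixes$timestamp)))
    eligible <- which(dt <= 120 & fixes$mode != "in_vehicle")
    eligible <- setdiff(eligible, c(1L, n))
    n_spk <- min(rbinom(1, n, spec$spike_rate_per_1000 / 1000),
                 length(eligible))
    if (n_spk > 0) {
      spike_idx <- sort(sample(eligible, n_spk))
      r <- runif(n_spk, spec$spike_min_m, spec$spike_max_m)
      th <- runif(n_spk, 0, 2 * pi)
      ex[spike_idx] <- r * sin(th)
      ey[spike_idx] <- r * cos(th)
    }
  }

  xn <- fixes$x + ex; yn <- fixes$y + ey
  ll <- aeq_unproject(xn, yn, home[1], home[2])
  trace_df <- tibble::tibble(
    timestamp = fixes$timestamp, lat = ll[, "lat"], lon = ll[, "lon"],
    speed_kmh = fixes$speed_kmh, accuracy = 95)
  trace <- gps_trace(participant_id, trace_df, interval_s = interval_s,
                     tz = tz)

  # recorded days: local dates with any fix truly beyond the home geofence
  away <- sqrt(fixes$x^2 + fixes$y^2) > 30
  rec_days <- unique(as.character(lubridate::as_date(
    lubridate::with_tz(fixes$timestamp[away], tz))))

  # --- diary (patients only) -----------------------------------------------
  diary <- tibble::tibble(start = day0[integer(0)], accompaniment = character())
  if (group == "patient" && nrow(truth_outings) > 0) {
    real <- truth_outings[!truth_outings$is_stroll, ]
    keep <- runif(nrow(real)) >= spec$diary_omission
    real <- real[keep, , drop = FALSE]
    if (nrow(real) > 0) {
      jit <- rnorm(nrow(real), 0, spec$diary_jitter_sd_min * 60)
      jit <- pmin(pmax(jit, -1200), 1200)
      diary <- tibble::tibble(
        start = real$start + jit,
        accompaniment = real$condition)
    }
  }

  truth <- list(outings = truth_outings,
                fix_mode = fixes$mode,
                fix_outing = fixes$outing_id,
                spike_indices = spike_idx,
                recorded_days = rec_days,
                rate_factor = rate_f, dist_factor = dist_f,
                routes = routes, home = home)
  list(trace = trace, diary = diary, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' Builds the environment layer, scatters participant homes near its centre,
#' derives per-participant seeds deterministically from `seed`, and generates
#' every participant's trace, diary and truth.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; two calls with the same spec and seed produce
#'   identical cohorts.
#' @return A `gps_cohort` list: `spec`, `env`, `participants` (tibble),
#'   `traces`, `diaries`, `truths` (named lists), `seed`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  set.seed(seed)
  env <- generate_environment(spec$env_kind, spec$extent_m,
                              spec$landmark_count,
                              seed = sample.int(2147483646, 1))
  n <- spec$n_control + spec$n_patient
  ids <- c(sprintf("C%02d", seq_len(spec$n_control)),
           sprintf("P%02d", seq_len(spec$n_patient)))
  group <- rep(c("control", "patient"), c(spec$n_control, spec$n_patient))
  n3c <- round(spec$frac_interval3[["control"]] * spec$n_control)
  n3p <- round(spec$frac_interval3[["patient"]] * spec$n_patient)
  interval_s <- c(rep(c(3L, 5L), c(n3c, spec$n_control - n3c)),
                  rep(c(3L, 5L), c(n3p, spec$n_patient - n3p)))
  hx <- runif(n, -spec$extent_m / 6, spec$extent_m / 6)
  hy <- runif(n, -spec$extent_m / 6, spec$extent_m / 6)
  hll <- aeq_unproject(hx, hy, env$center[1], env$center[2])
  disoriented <- ifelse(group == "patient",
                        runif(n) < spec$p_disorient, FALSE)
  seeds <- sample.int(2147483646, n)
  participants <- tibble::tibble(
    participant_id = ids, group = group, disoriented = disoriented,
    interval_s = interval_s, home_lat = hll[, "lat"], home_lon = hll[, "lon"],
    seed = seeds)
  traces <- list(); diaries <- list(); truths <- list()
  for (i in seq_len(n)) {
    p <- generate_participant(spec, group[i],
                              c(hll[i, "lat"], hll[i, "lon"]),
                              interval_s[i], ids[i], seeds[i], env = env)
    traces[[ids[i]]] <- p$trace
    diaries[[ids[i]]] <- p$diary
    truths[[ids[i]]] <- p$truth
  }
  structure(list(spec = spec, env = env, participants = participants,
                 traces = traces, diaries = diaries, truths = truths,
                 seed = seed),
            class = "gps_cohort")
}

#' @export
print.gps_cohort <- function(x, ...) {
  cat(sprintf("<gps_cohort> %d participants (%d control, %d patient), %d days\n",
              nrow(x$participants),
              sum(x$participants$group == "control"),
              sum(x$participants$group == "patient"),
              x$spec$tracking_days))
  invisible(x)
}

#' Write a cohort to a directory in the pipeline's file dialects
#'
#' Produces `manifest.csv`, per-participant `traces/<id>.csv` and
#' `diaries/<id>.csv`, the environment GeoJSON layers, and per-participant
#' planted-outing tables under `truth/` for reference.
#'
#' @param cohort A `gps_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  for (d in file.path(dir, c("", "traces", "diaries", "truth")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$participants
  man$trace_file <- file.path("traces", paste0(man$participant_id, ".csv"))
  man$diary_file <- file.path("diaries", paste0(man$participant_id, ".csv"))
  readr::write_csv(man, file.path(dir, "manifest.csv"), progress = FALSE)
  write_environment_geojson(cohort$env,
                            file.path(dir, "landmarks.geojson"),
                            file.path(dir, "roads.geojson"))
  for (id in man$participant_id) {
    write_gps_csv(cohort$traces[[id]], file.path(dir, "traces",
                                                 paste0(id, ".csv")))
    write_diary_csv(cohort$diaries[[id]], file.path(dir, "diaries",
                                                    paste0(id, ".csv")))
    tr <- cohort$truths[[id]]$outings
    tr$start <- format(tr$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    tr$end <- format(tr$end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    readr::write_csv(tr, file.path(dir, "truth", paste0(id, "_outings.csv")),
                     progress = FALSE)
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Ground truth is not reloaded; this is the entry point the pipeline uses
#' for real (or simulated-on-disk) data.
#'
#' @param dir Cohort directory.
#' @param tz Time zone for local-day logic.
#' @return A `gps_cohort` without `truths` (and with `spec = NULL`).
#' @export
read_cohort <- function(dir, tz = "Europe/London") {
  man <- readr::read_csv(file.path(dir, "manifest.csv"),
                         show_col_types = FALSE, progress = FALSE)
  env <- read_environment_geojson(file.path(dir, "landmarks.geojson"),
                                  file.path(dir, "roads.geojson"))
  traces <- list(); diaries <- list()
  for (i in seq_len(nrow(man))) {
    id <- man$participant_id[i]
    traces[[id]] <- tryCatch(
      read_gps_csv(file.path(dir, man$trace_file[i]), id,
                   interval_s = man$interval_s[i], tz = tz),
      error = function(e) {
        gm_log("warning", sprintf("%s: %s (kept as empty trace)", id,
                                  conditionMessage(e)))
        gps_trace(id, tibble::tibble(
          timestamp = as.POSIXct(character(), tz = "UTC"),
          lat = numeric(), lon = numeric()),
          interval_s = man$interval_s[i], tz = tz)
      })
    diaries[[id]] <- read_diary_csv(file.path(dir, man$diary_file[i]))
  }
  structure(list(spec = NULL, env = env,
                 participants = tibble::as_tibble(man),
                 traces = traces, diaries = diaries, truths = NULL,
                 seed = NA_integer_),
            class = "gps_cohort")
}
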