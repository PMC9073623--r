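## Trace preprocessing: day cleaning, spike smoothing, transport-mode
## classification over fixed-duration time windows.

dist_to_home <- function(fixes, home) {
  haversine_m(fixes$lat, fixes$lon, home[1], home[2])
}

#' Remove days with no outdoor navigation
#'
#' A local calendar day is removed when no fix on that day lies farther than
#' `home_radius_m` from the home centroid (or the day has no fixes at all).
#'
#' @param trace A [gps_trace()].
#' @param home c(lat, lon) home centroid.
#' @param home_radius_m Home geofence radius, m.
#' @return A list: `trace` (cleaned), `removed_days`, `recorded_days`
#'   (character dates kept), `kept_rows` (indices into the input fixes),
#'   `empty` (TRUE when every day was removed; the caller decides exclusion).
#' @export
clean_days <- function(trace, home, home_radius_m = 30) {
  stopifnot(inherits(trace, "gps_trace"))
  fixes <- trace$fixes
  if (nrow(fixes) == 0)
    return(list(trace = trace, removed_days = character(),
                recorded_days = character(), kept_rows = integer(),
                empty = TRUE))
  day <- as.character(lubridate::as_date(
    lubridate::with_tz(fixes$timestamp, trace$tz)))
  away <- dist_to_home(fixes, home) > home_radius_m
  keep_days <- unique(day[away])
  removed <- setdiff(unique(day), keep_days)
  keep <- day %in% keep_days
  out <- trace
  out$fixes <- fixes[keep, , drop = FALSE]
  if (length(removed))
    gm_log("info", sprintf("%s: removed %d day(s) with no outdoor navigation",
                           trace$participant_id, length(removed)))
  list(trace = out, removed_days = sort(removed),
       recorded_days = sort(keep_days), kept_rows = which(keep),
       empty = length(keep_days) == 0)
}

#' Remove GPS spikes by a maximum-speed distance threshold
#'
#' Scans consecutive fixes: a fix whose geodesic distance from the last
#' retained fix exceeds what could be covered at `vmax_kmh` in the elapsed
#' time is removed as a sensor artifact; the scan continues from the last
#' retained fix. Idempotent.
#'
#' @param trace A [gps_trace()].
#' @param vmax_kmh Maximum plausible travel speed, km/h.
#' @return A list: `trace` (smoothed), `removed` (indices into the input
#'   fixes).
#' @export
remove_spikes <- function(trace, vmax_kmh = 200) {
  stopifnot(inherits(trace, "gps_trace"), vmax_kmh > 0)
  fixes <- trace$fixes
  if (nrow(fixes) < 2) return(list(trace = trace, removed = integer()))
  keep <- spike_scan_cpp(fixes$lat, fixes$lon, as.numeric(fixes$timestamp),
                         vmax_kmh / 3.6)
  out <- trace
  out$fixes <- fixes[keep, , drop = FALSE]
  if (any(!keep))
    gm_log("info", sprintf("%s: removed %d spike fix(es)",
                           trace$participant_id, sum(!keep)))
  list(trace = out, removed = which(!keep))
}

## per-fix speed in km/h: device field when allowed, else recomputed from
## consecutive geodesic displacements within a recording run
fix_speeds_kmh <- function(fixes, gap_s, use_device_speed = TRUE) {
  n <- nrow(fixes)
  if (n == 0) return(numeric())
  has_device <- "speed_kmh" %in% names(fixes) && !all(is.na(fixes$speed_kmh))
  if (use_device_speed && has_device) {
    sp <- fixes$speed_kmh
    if (!anyNA(sp)) return(sp)
  } else {
    sp <- rep(NA_real_, n)
  }
  if (n >= 2) {
    dt <- diff(as.numeric(fixes$timestamp))
    d <- haversine_m(fixes$lat[-n], fixes$lon[-n],
                     fixes$lat[-1], fixes$lon[-1])
    comp <- c(NA_real_, ifelse(dt > gap_s, NA_real_, d / dt * 3.6))
    # first fix of each run inherits the following pair's speed
    run_start <- c(TRUE, dt > gap_s)
    idx <- which(run_start)
    comp[idx] <- comp[pmin(idx + 1L, n)]
    sp[is.na(sp)] <- comp[is.na(sp)]
  }
  sp
}

#' Group fixes into time windows and classify transport modes
#'
#' Windows tile each recording run (runs split at gaps > `gap_s`): 3 fixes
#' per window at 3 s sampling (9 s), 2 fixes at 5 s (10 s). A window is
#' `stationary` when its mean speed is below `stationary_max_mean`, `by_foot`
#' when mean < `foot_max_mean` and max < `foot_max_max`, else `in_vehicle`.
#' Incomplete trailing windows are classified when they carry at least one
#' speed estimate and dropped (logged) otherwise.
#'
#' @param trace A preprocessed [gps_trace()].
#' @param stationary_max_mean,foot_max_mean,foot_max_max Thresholds, km/h.
#' @param gap_s Recording-gap threshold, s.
#' @param use_device_speed Prefer the device speed field when present.
#' @return A list: `windows` (tibble with start/end, n_fixes, mean/max speed,
#'   mode) and `fix_window` (window id per fix, NA for dropped fixes).
#' @export
window_and_classify <- function(trace, stationary_max_mean = 1,
                                foot_max_mean = 7, foot_max_max = 12,
                                gap_s = 120, use_device_speed = TRUE) {
  stopifnot(inherits(trace, "gps_trace"))
  fixes <- trace$fixes
  n <- nrow(fixes)
  empty <- list(windows = tibble::tibble(
    window_id = integer(), start = fixes$timestamp[0],
    end = fixes$timestamp[0], n_fixes = integer(), mean_speed = numeric(),
    max_speed = numeric(), mode = character()),
    fix_window = integer())
  if (n == 0) return(empty)
  k <- if (trace$interval_s == 3) 3L else 2L
  dt <- c(Inf, diff(as.numeric(fixes$timestamp)))
  run_id <- cumsum(dt > gap_s)
  pos_in_run <- stats::ave(seq_len(n), run_id, FUN = seq_along)
  win <- paste0(run_id, ".", (pos_in_run - 1L) %/% k)
  win_id <- match(win, unique(win))
  sp <- fix_speeds_kmh(fixes, gap_s, use_device_speed)
  wtab <- tibble::tibble(win_id = win_id, t = fixes$timestamp, sp = sp)
  agg <- dplyr::summarise(dplyr::group_by(wtab, win_id),
                          start = min(.data$t), end = max(.data$t),
                          n_fixes = dplyr::n(),
                          mean_speed = mean(.data$sp, na.rm = TRUE),
                          max_speed = suppressWarnings(
                            max(.data$sp, na.rm = TRUE)),
                          n_speed = sum(!is.na(.data$sp)),
                          .groups = "drop")
  drop <- agg$n_speed == 0
  if (any(drop))
    gm_log("debug", sprintf("%s: dropped %d window(s) without speed estimate",
                            trace$participant_id, sum(drop)))
  agg$mean_speed[drop] <- NA_real_
  agg$max_speed[drop] <- NA_real_
  mode <- ifelse(agg$mean_speed < stationary_max_mean, "stationary",
          ifelse(agg$mean_speed < foot_max_mean &
                 agg$max_speed < foot_max_max, "by_foot", "in_vehicle"))
  mode[drop] <- NA_character_
  windows <- tibble::tibble(window_id = agg$win_id, start = agg$start,
                            end = agg$end, n_fixes = agg$n_fixes,
                            mean_speed = agg$mean_speed,
                            max_speed = agg$max_speed, mode = mode)
  fix_window <- win_id
  fix_window[win_id %in% agg$win_id[drop]] <- NA_integer_
  list(windows = windows, fix_window = fix_window)
}

#' Full preprocessing of one trace
#'
#' Day cleaning, spike removal, then window classification; the window mode is
#' attached to every fix (`mode` column) for the downstream outing metrics.
#'
#' @param trace A [gps_trace()].
#' @param home c(lat, lon).
#' @param config A [pipeline_config()].
#' @return A list: `trace` (fixes carry `mode`), `windows`, `fix_window`,
#'   `recorded_days`, `removed_days`, `spike_rows` (indices into the
#'   day-cleaned fixes), `kept_rows` (final indices into the raw fixes),
#'   `excluded` (no usable days).
#' @export
preprocess_trace <- function(trace, home, config = pipeline_config()) {
  cl <- clean_days(trace, home, config$home_radius_m)
  if (cl$empty)
    return(list(trace = cl$trace, windows = NULL, fix_window = integer(),
                recorded_days = character(), removed_days = cl$removed_days,
                spike_rows = integer(), kept_rows = integer(),
                excluded = TRUE))
  sm <- remove_spikes(cl$trace, config$spike_vmax_kmh)
  wc <- window_and_classify(sm$trace,
                            stationary_max_mean = config$stationary_max_mean,
                            foot_max_mean = config$foot_max_mean,
                            foot_max_max = config$foot_max_max,
                            gap_s = config$gap_s,
                            use_device_speed = config$use_device_speed)
  out <- sm$trace
  out$fixes$mode <- windows_mode_of(wc, nrow(out$fixes))
  kept <- cl$kept_rows
  if (length(sm$removed)) kept <- kept[-sm$removed]
  list(trace = out, windows = wc$windows, fix_window = wc$fix_window,
       recorded_days = cl$recorded_days, removed_days = cl$removed_days,
       spike_rows = sm$removed, kept_rows = kept, excluded = FALSE)
}

windows_mode_of <- function(wc, n) {
  mode <- rep(NA_character_, n)
  ok <- !is.na(wc$fix_window)
  mode[ok] <- wc$windows$mode[wc$fix_window[ok]]
  mode
}
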