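## Pipeline configuration. Every tunable the pipeline uses is surfaced here
## with its default; nothing is hard-coded at the call sites.

#' Pipeline configuration
#'
#' Builds the configuration object consumed by every pipeline stage. Defaults
#' follow the study design the package implements: a 30 m home geofence (3 SD
#' of ~10 m GPS error), 100 m minimum outing path, a 06:00-18:00 day band,
#' 200 km/h spike speed ceiling, landmark/road/entropy buffer radii of
#' 50 + 30, 30 and 2000 + 30 m, and 36 orientation-entropy bins of 10 degrees.
#'
#' @param home_radius_m Home geofence radius in meters.
#' @param min_outing_path_m Minimum cumulative path length of an outing, m.
#' @param min_outing_displacement_m Minimum displacement from home an outing
#'   must reach (default home radius + 3 SD of GPS error): a candidate that
#'   never gets clear of the geofence by more than measurement error is
#'   at-home noise wander, however much path it accumulates.
#' @param outing_rule How "minimum distance covered" is read: cumulative
#'   `"path"` length (default) or maximum `"displacement"` from home.
#' @param min_home_dwell_s Minimum duration of an at-home run for it to close
#'   an outing; shorter home "bounces" (typically single noisy fixes) are
#'   absorbed into the surrounding outing.
#' @param day_band Length-2 character vector of clock times (HH:MM), the
#'   inclusive daytime band; outings starting outside it are nighttime.
#' @param tz Time zone used for local calendar days and clock-time bands.
#' @param spike_vmax_kmh Maximum plausible travel speed for the spike filter.
#' @param gap_s Recording gap threshold in seconds (the device stops recording
#'   after 2 min without movement).
#' @param stationary_max_mean,foot_max_mean,foot_max_max Window-classification
#'   speed thresholds in km/h (mean < 1 -> stationary; mean < 7 and max < 12
#'   -> by foot; else in vehicle).
#' @param use_device_speed Use the device-reported speed field when present
#'   (else recompute from consecutive positions).
#' @param landmark_core_radius_m,error_buffer_m,road_radius_m,entropy_core_radius_m
#'   Buffer construction terms: landmark radius = core 50 + error 30 = 80 m;
#'   entropy radius = core 2000 + error 30 = 2030 m; road radius = 30 m.
#' @param entropy_bins Number of angular bins for orientation entropy.
#' @param entropy_step_m Sub-segment length used to clip road edges to the
#'   entropy buffer.
#' @param buffer_simplify_m Minimum spacing when thinning a walking trajectory
#'   before buffering (0 disables).
#' @param dfd_units `"meters"` (geodesic) or `"degrees"` (Euclidean on raw
#'   coordinates) for the discrete Frechet distance.
#' @param dfd_max_points Trajectories are downsampled by uniform stride to at
#'   most this many points before the Frechet computation.
#' @param diary_match_window_min Diary-to-outing matching window (+/- min).
#' @param alpha Significance level for omnibus/post hoc gating.
#' @param normality_alpha Shapiro-Wilk level for the normality gate.
#' @param seed Integer seed making a pipeline run reproducible.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(home_radius_m = 30,
                            min_outing_path_m = 100,
                            min_outing_displacement_m = 60,
                            outing_rule = c("path", "displacement"),
                            min_home_dwell_s = 120,
                            day_band = c("06:00", "18:00"),
                            tz = "Europe/London",
                            spike_vmax_kmh = 200,
                            gap_s = 120,
                            stationary_max_mean = 1,
                            foot_max_mean = 7,
                            foot_max_max = 12,
                            use_device_speed = TRUE,
                            landmark_core_radius_m = 50,
                            error_buffer_m = 30,
                            road_radius_m = 30,
                            entropy_core_radius_m = 2000,
                            entropy_bins = 36,
                            entropy_step_m = 10,
                            buffer_simplify_m = 5,
                            dfd_units = c("meters", "degrees"),
                            dfd_max_points = 500,
                            diary_match_window_min = 30,
                            alpha = 0.05,
                            normality_alpha = 0.05,
                            seed = 1L) {
  cfg <- list(
    schema_version = 1L,
    home_radius_m = home_radius_m,
    min_outing_path_m = min_outing_path_m,
    min_outing_displacement_m = min_outing_displacement_m,
    outing_rule = match.arg(outing_rule),
    min_home_dwell_s = min_home_dwell_s,
    day_band = day_band,
    tz = tz,
    spike_vmax_kmh = spike_vmax_kmh,
    gap_s = gap_s,
    stationary_max_mean = stationary_max_mean,
    foot_max_mean = foot_max_mean,
    foot_max_max = foot_max_max,
    use_device_speed = use_device_speed,
    landmark_core_radius_m = landmark_core_radius_m,
    error_buffer_m = error_buffer_m,
    road_radius_m = road_radius_m,
    entropy_core_radius_m = entropy_core_radius_m,
    entropy_bins = entropy_bins,
    entropy_step_m = entropy_step_m,
    buffer_simplify_m = buffer_simplify_m,
    dfd_units = match.arg(dfd_units),
    dfd_max_points = dfd_max_points,
    diary_match_window_min = diary_match_window_min,
    alpha = alpha,
    normality_alpha = normality_alpha,
    seed = as.integer(seed)
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  radii <- c(cfg$home_radius_m, cfg$landmark_core_radius_m + cfg$error_buffer_m,
             cfg$road_radius_m, cfg$entropy_core_radius_m + cfg$error_buffer_m)
  if (any(radii <= 0)) stop("all radii must be > 0", call. = FALSE)
  if (cfg$spike_vmax_kmh <= 0) stop("spike_vmax_kmh must be > 0", call. = FALSE)
  if (cfg$entropy_bins < 2) stop("entropy_bins must be >= 2", call. = FALSE)
  if (!all(grepl("^\\d{2}:\\d{2}$", cfg$day_band)) || length(cfg$day_band) != 2)
    stop("day_band must be two HH:MM clock times", call. = FALSE)
  hm <- strsplit(cfg$day_band, ":")
  bad <- vapply(hm, function(p) {
    h <- as.integer(p[1]); m <- as.integer(p[2])
    is.na(h) || is.na(m) || h > 23 || m > 59
  }, logical(1))
  if (any(bad)) stop("day_band must be valid clock times", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of [pipeline_config()];
#' unknown keys are an error so typos do not silently fall back to defaults.
#' An optional `column_map` section (timestamp/lat/lon/speed/accuracy) is
#' carried through for adapting device-native CSV exports.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$schema_version) && raw$schema_version != 1L)
    stop("unsupported config schema_version: ", raw$schema_version, call. = FALSE)
  raw$schema_version <- NULL
  column_map <- raw$column_map
  raw$column_map <- NULL
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- do.call(pipeline_config, raw)
  cfg$column_map <- column_map
  cfg
}

#' Write a pipeline configuration to YAML
#'
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> (schema", x$schema_version, ")\n")
  for (nm in setdiff(names(x), "schema_version"))
    cat(sprintf("  %-24s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}
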