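## Readers/writers for the package's on-disk dialects: GPS fix CSV (ISO-8601
## timestamps, WGS84 decimal degrees), diary CSV, and GeoJSON environment
## layers (Point landmarks, LineString roads). GeoJSON is parsed with
## jsonlite; only the small feature subset used here is supported.

log_levels <- c(debug = 1L, info = 2L, warning = 3L, error = 4L)

gm_log <- function(level, ...) {
  threshold <- getOption("gpsmobility.log_level", "info")
  if (log_levels[[level]] >= log_levels[[threshold]])
    message(sprintf("[%s] %s", level, paste0(...)))
  invisible(NULL)
}

#' Construct a GPS trace
#'
#' A `gps_trace` holds one participant's ordered fix stream plus metadata.
#'
#' @param participant_id Identifier string.
#' @param fixes A data frame with columns `timestamp` (POSIXct, UTC), `lat`,
#'   `lon`, and optionally `speed_kmh`, `accuracy`.
#' @param interval_s Nominal sampling interval in seconds (3 or 5).
#' @param tz Time zone for local-day logic.
#' @return A `gps_trace` object.
#' @export
gps_trace <- function(participant_id, fixes, interval_s = 3, tz = "Europe/London") {
  stopifnot(interval_s %in% c(3, 5))
  fixes <- tibble::as_tibble(fixes)
  if (!"speed_kmh" %in% names(fixes)) fixes$speed_kmh <- NA_real_
  if (!"accuracy" %in% names(fixes)) fixes$accuracy <- NA_real_
  if (nrow(fixes) > 1 && any(diff(as.numeric(fixes$timestamp)) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  structure(
    list(participant_id = participant_id,
         interval_s = interval_s,
         tz = tz,
         fixes = fixes),
    class = "gps_trace")
}

#' @export
print.gps_trace <- function(x, ...) {
  cat(sprintf("<gps_trace> %s: %d fixes @ %ds", x$participant_id,
              nrow(x$fixes), x$interval_s))
  if (nrow(x$fixes))
    cat(sprintf(" [%s .. %s]", format(min(x$fixes$timestamp)),
                format(max(x$fixes$timestamp))))
  cat("\n")
  invisible(x)
}

#' Read a GPS fix stream from CSV
#'
#' Expects a header with `timestamp` (ISO-8601, UTC), `lat`, `lon` and
#' optional `speed_kmh` / `accuracy` columns (a `column_map` in the config can
#' rename device-native headers). Rows with unparseable timestamps or
#' out-of-range coordinates are dropped with a warning; duplicate timestamps
#' collapse to their first occurrence; fixes are returned in time order.
#'
#' @param path CSV file path.
#' @param participant_id Identifier recorded on the trace.
#' @param interval_s Sampling interval in seconds (3 or 5).
#' @param tz Time zone for downstream local-day logic.
#' @param column_map Optional named list mapping canonical names
#'   (timestamp/lat/lon/speed_kmh/accuracy) to file column names.
#' @return A [gps_trace()].
#' @export
read_gps_csv <- function(path, participant_id, interval_s = 3,
                         tz = "Europe/London", column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) stop("empty trace file: ", path, call. = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (src %in% names(df)) names(df)[names(df) == src] <- canon
    }
  }
  for (col in c("timestamp", "lat", "lon")) {
    if (!col %in% names(df))
      stop("missing mandatory column: ", col, call. = FALSE)
  }
  if (!inherits(df$timestamp, "POSIXct"))
    df$timestamp <- lubridate::ymd_hms(as.character(df$timestamp),
                                       tz = "UTC", quiet = TRUE)
  attr(df$timestamp, "tzone") <- "UTC"
  n0 <- nrow(df)
  ok <- !is.na(df$timestamp) & !is.na(df$lat) & !is.na(df$lon) &
    df$lat >= -90 & df$lat <= 90 & df$lon >= -180 & df$lon <= 180
  if (any(!ok)) {
    warning(sprintf("%s: dropped %d invalid row(s)", basename(path), sum(!ok)),
            call. = FALSE)
    df <- df[ok, , drop = FALSE]
  }
  df <- df[order(df$timestamp), , drop = FALSE]
  dup <- duplicated(df$timestamp)
  if (any(dup)) {
    gm_log("info", sprintf("%s: collapsed %d duplicate timestamp(s)",
                           basename(path), sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no usable fixes in ", path, call. = FALSE)
  gm_log("debug", sprintf("%s: %d of %d rows retained", basename(path),
                          nrow(df), n0))
  keep <- intersect(c("timestamp", "lat", "lon", "speed_kmh", "accuracy"),
                    names(df))
  gps_trace(participant_id, df[keep], interval_s = interval_s, tz = tz)
}

#' Write a GPS trace to CSV
#'
#' Inverse of [read_gps_csv()] on valid files.
#'
#' @param trace A [gps_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gps_csv <- function(trace, path) {
  df <- trace$fixes
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Construct an environment layer
#'
#' Landmark points plus a road network (nodes and straight-segment edges).
#'
#' @param landmarks Data frame with `lat`, `lon` (may have zero rows).
#' @param nodes Data frame with `id`, `lat`, `lon`.
#' @param edges Data frame with `from`, `to` node ids.
#' @param center Optional c(lat, lon) reference point of the layer.
#' @return An `environment_layer` object.
#' @export
environment_layer <- function(landmarks, nodes, edges,
                              center = NULL) {
  landmarks <- tibble::as_tibble(landmarks)
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) && !all(c(edges$from, edges$to) %in% nodes$id))
    stop("edge references a missing node id", call. = FALSE)
  if (is.null(center)) {
    center <- if (nrow(nodes)) c(mean(nodes$lat), mean(nodes$lon))
      else if (nrow(landmarks)) c(mean(landmarks$lat), mean(landmarks$lon))
      else c(0, 0)
  }
  structure(list(landmarks = landmarks, nodes = nodes, edges = edges,
                 center = center),
            class = "environment_layer")
}

#' @export
print.environment_layer <- function(x, ...) {
  cat(sprintf("<environment_layer> %d landmarks, %d nodes, %d edges\n",
              nrow(x$landmarks), nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Node degrees of the road network
#'
#' @param env An [environment_layer()].
#' @return Named integer vector: number of road legs at each node.
#' @export
node_degree <- function(env) {
  ids <- env$nodes$id
  deg <- table(factor(c(env$edges$from, env$edges$to), levels = ids))
  setNames(as.integer(deg), ids)
}

#' Read landmark and road layers from GeoJSON
#'
#' Landmarks must be Point features; roads LineString features whose
#' properties carry `from`/`to` node identifiers (endpoint coordinates define
#' the node positions). Coordinates are WGS84 lon/lat as in the GeoJSON spec.
#'
#' @param landmarks_path,roads_path GeoJSON FeatureCollection files.
#' @return An [environment_layer()].
#' @export
read_environment_geojson <- function(landmarks_path, roads_path) {
  lm_json <- jsonlite::read_json(landmarks_path)
  rd_json <- jsonlite::read_json(roads_path)
  lm <- purrr::map_dfr(lm_json$features, function(f) {
    if (!identical(f$geometry$type, "Point"))
      stop("landmark feature is not a Point: ", f$geometry$type, call. = FALSE)
    tibble::tibble(lon = f$geometry$coordinates[[1]],
                   lat = f$geometry$coordinates[[2]])
  })
  if (nrow(lm) == 0) lm <- tibble::tibble(lon = numeric(), lat = numeric())
  nodes <- list(); edges <- list()
  for (f in rd_json$features) {
    if (!identical(f$geometry$type, "LineString"))
      stop("road feature is not a LineString: ", f$geometry$type, call. = FALSE)
    coords <- f$geometry$coordinates
    from <- f$properties$from; to <- f$properties$to
    if (is.null(from) || is.null(to))
      stop("road feature lacks from/to node ids", call. = FALSE)
    a <- coords[[1]]; b <- coords[[length(coords)]]
    nodes[[as.character(from)]] <- c(lon = a[[1]], lat = a[[2]])
    nodes[[as.character(to)]] <- c(lon = b[[1]], lat = b[[2]])
    edges[[length(edges) + 1L]] <- tibble::tibble(from = as.character(from),
                                                 to = as.character(to))
  }
  node_df <- if (length(nodes)) {
    tibble::tibble(id = names(nodes),
                   lon = vapply(nodes, `[[`, 0, "lon"),
                   lat = vapply(nodes, `[[`, 0, "lat"))
  } else tibble::tibble(id = character(), lon = numeric(), lat = numeric())
  edge_df <- if (length(edges)) dplyr::bind_rows(edges)
    else tibble::tibble(from = character(), to = character())
  environment_layer(lm, node_df, edge_df)
}

#' Write an environment layer to GeoJSON
#'
#' @param env An [environment_layer()].
#' @param landmarks_path,roads_path Output files.
#' @return Invisibly, the two paths.
#' @export
write_environment_geojson <- function(env, landmarks_path, roads_path) {
  lm_feats <- purrr::pmap(env$landmarks, function(lon, lat, ...) {
    list(type = "Feature", properties = list(),
         geometry = list(type = "Point", coordinates = c(lon, lat)))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = lm_feats),
    landmarks_path, auto_unbox = TRUE, digits = 10)
  node_idx <- setNames(seq_len(nrow(env$nodes)), env$nodes$id)
  rd_feats <- purrr::pmap(env$edges, function(from, to, ...) {
    a <- env$nodes[node_idx[[as.character(from)]], ]
    b <- env$nodes[node_idx[[as.character(to)]], ]
    list(type = "Feature",
         properties = list(from = as.character(from), to = as.character(to)),
         geometry = list(type = "LineString",
                         coordinates = list(c(a$lon, a$lat), c(b$lon, b$lat))))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = rd_feats),
    roads_path, auto_unbox = TRUE, digits = 10)
  invisible(c(landmarks_path, roads_path))
}

#' Read a navigation diary from CSV
#'
#' Columns: `start` (ISO-8601 outing start), `accompaniment`
#' (alone/accompanied), optional `note`.
#'
#' @param path CSV path.
#' @return A tibble (zero rows if the file is empty or absent).
#' @export
read_diary_csv <- function(path) {
  if (!file.exists(path))
    return(tibble::tibble(start = as.POSIXct(character(), tz = "UTC"),
                          accompaniment = character()))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0)
    return(tibble::tibble(start = as.POSIXct(character(), tz = "UTC"),
                          accompaniment = character()))
  if (!all(c("start", "accompaniment") %in% names(df)))
    stop("diary needs start and accompaniment columns", call. = FALSE)
  if (!inherits(df$start, "POSIXct"))
    df$start <- lubridate::ymd_hms(as.character(df$start), tz = "UTC",
                                   quiet = TRUE)
  attr(df$start, "tzone") <- "UTC"
  bad <- !df$accompaniment %in% c("alone", "accompanied")
  if (any(bad)) stop("accompaniment must be alone/accompanied", call. = FALSE)
  tibble::as_tibble(df)
}

#' Write a navigation diary to CSV
#' @param diary Tibble with `start`, `accompaniment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diary_csv <- function(diary, path) {
  diary$start <- format(diary$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(diary, path, progress = FALSE)
  invisible(path)
}
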