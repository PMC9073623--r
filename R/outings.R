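## Home-anchored outing segmentation and labelling. An outing runs from the
## moment the trace leaves the 30 m home geofence to its return, and must
## cover a minimum path length (100 m by default) to count.

#' Segment a preprocessed trace into home-to-home outings
#'
#' Fixes within `home_radius_m` of the home centroid are "at home". An
#' at-home run closes outings when it lasts at least `min_home_dwell_s`, is
#' adjacent to a recording gap, or touches a trace end; shorter home bounces
#' (typically single noise-flipped fixes) are absorbed into the surrounding
#' outing. A recording gap (> `gap_s`) also closes the current outing when
#' any fix within `min_home_dwell_s` on either side of it is at home (the
#' trace went quiet while near home); gaps without home evidence are treated
#' as in-outing signal loss. Candidates whose cumulative geodesic path length
#' (or maximum displacement from home, per `rule`) stays below
#' `min_outing_path_m` are discarded.
#'
#' @param trace A preprocessed [gps_trace()] (spikes removed; fixes may carry
#'   a `mode` column which is retained).
#' @param home c(lat, lon) home centroid.
#' @param home_radius_m,min_outing_path_m,min_outing_displacement_m,min_home_dwell_s,gap_s
#'   See [pipeline_config()].
#' @param rule `"path"` or `"displacement"`.
#' @return A tibble, one row per outing: `start`, `end`, `path_length_m`
#'   (anchored at the home centroid), `outside_path_m` (the raw
#'   outside-geofence path the length filter uses), `max_displacement_m`,
#'   `n_fixes`, `truncated`, and a `fixes` list column.
#' @export
detect_outings <- function(trace, home, home_radius_m = 30,
                           min_outing_path_m = 100,
                           min_outing_displacement_m = 60,
                           min_home_dwell_s = 120,
                           gap_s = 120, rule = c("path", "displacement")) {
  stopifnot(inherits(trace, "gps_trace"))
  rule <- match.arg(rule)
  fixes <- trace$fixes
  n <- nrow(fixes)
  empty <- tibble::tibble(participant_id = character(), start = fixes$timestamp[0],
                          end = fixes$timestamp[0], path_length_m = numeric(),
                          outside_path_m = numeric(),
                          max_displacement_m = numeric(), n_fixes = integer(),
                          truncated = logical(), fixes = list())
  if (n == 0) return(empty)
  tnum <- as.numeric(fixes$timestamp)
  at_home <- dist_to_home(fixes, home) <= home_radius_m
  gap_before <- c(FALSE, diff(tnum) > gap_s)

  # qualifying gap cuts: home evidence immediately adjacent to the gap (a
  # wider window would reach back through a short outing to its departure
  # fixes and split it at a mid-outing stop)
  evidence_s <- 15
  cut_before <- rep(FALSE, n)
  for (i in which(gap_before)) {
    before <- which(tnum >= tnum[i - 1L] - evidence_s & tnum <= tnum[i - 1L])
    after <- which(tnum >= tnum[i] & tnum <= tnum[i] + evidence_s)
    if (any(at_home[c(before, after)])) cut_before[i] <- TRUE
  }
  seg_id <- cumsum(cut_before)

  # closing at-home runs (within a segment)
  r <- rle(paste0(seg_id, ":", at_home))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_home_run <- at_home[starts]
  run_closing <- rep(FALSE, length(starts))
  for (j in which(is_home_run)) {
    a <- starts[j]; b <- ends[j]
    run_closing[j] <- (tnum[b] - tnum[a]) >= min_home_dwell_s ||
      a == 1L || b == n || gap_before[a] ||
      (b < n && gap_before[b + 1L]) || cut_before[a] ||
      (b < n && cut_before[b + 1L])
  }

  closing <- rep(FALSE, n)
  for (j in which(run_closing)) closing[starts[j]:ends[j]] <- TRUE

  out <- list()
  for (s in unique(seg_id)) {
    idx <- which(seg_id == s)
    cl <- closing[idx]
    rr <- rle(cl)
    re <- cumsum(rr$lengths); rs <- re - rr$lengths + 1L
    for (j in seq_along(rr$values)) {
      if (rr$values[j]) next # a closing home run, not an outing
      a <- idx[rs[j]]; b <- idx[re[j]]
      if (!any(!at_home[a:b])) next
      lead_ok <- rs[j] > 1L # preceding closing run inside segment
      trail_ok <- re[j] < length(idx)
      ai <- if (lead_ok) a - 1L else a
      bi <- if (trail_ok) b + 1L else b
      sub <- fixes[ai:bi, , drop = FALSE]
      plen <- path_length_m(sub$lat, sub$lon)
      disp <- max(dist_to_home(sub, home))
      truncated <- (!lead_ok && !at_home[a]) || (!trail_ok && !at_home[b])
      # reported length is anchored to the home centroid (the journey starts
      # and ends at home); the min-length filter below stays on the
      # outside-geofence path so noise excursions near the fence gain nothing
      anchor <- 0
      if (at_home[ai]) anchor <- anchor + dist_to_home(sub[1, ], home)
      if (at_home[bi]) anchor <- anchor + dist_to_home(sub[nrow(sub), ], home)
      out[[length(out) + 1L]] <- tibble::tibble(
        participant_id = trace$participant_id,
        start = sub$timestamp[1], end = sub$timestamp[nrow(sub)],
        path_length_m = plen + anchor, outside_path_m = plen,
        max_displacement_m = disp,
        n_fixes = nrow(sub), truncated = truncated, fixes = list(sub))
    }
  }
  if (!length(out)) return(empty)
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$start)
  keep <- if (rule == "path") res$outside_path_m >= min_outing_path_m
    else res$max_displacement_m >= min_outing_path_m
  # a candidate must also get clear of the geofence by more than measurement
  # error: sustained 3 SD position offsets can accumulate 100+ m of
  # tangential noise path while never leaving the fence's neighbourhood
  keep <- keep & res$max_displacement_m >= min_outing_displacement_m
  res[keep, , drop = FALSE]
}

#' Classify outing start times into day/night bands
#'
#' Daytime is the inclusive clock-time band `day_band` (06:00-18:00 by
#' default, minute resolution, so 18:00 is daytime and 18:01 nighttime);
#' classification uses the outing's start time in the local time zone.
#'
#' @param start POSIXct vector of outing start times.
#' @param day_band Length-2 HH:MM character vector.
#' @param tz Local time zone.
#' @return Character vector, `"day"` or `"night"`.
#' @export
classify_band <- function(start, day_band = c("06:00", "18:00"),
                          tz = "Europe/London") {
  hm <- vapply(strsplit(day_band, ":"),
               function(p) as.integer(p[1]) * 60L + as.integer(p[2]),
               integer(1))
  lt <- lubridate::with_tz(start, tz)
  mins <- lubridate::hour(lt) * 60 + lubridate::minute(lt)
  ifelse(mins >= hm[1] & mins <= hm[2], "day", "night")
}

#' Label outings with diary accompaniment
#'
#' Each outing inherits the accompaniment of the diary entry whose start time
#' is nearest to the outing's start within +/- `window_min` minutes; a diary
#' entry is matched to at most one outing. Unmatched outings are `"unknown"`
#' and excluded from alone/accompanied splits.
#'
#' @param outings Outing tibble from [detect_outings()].
#' @param diary Tibble with `start`, `accompaniment` (may be empty).
#' @param window_min Matching half-window, minutes.
#' @return `outings` with an `accompaniment` column.
#' @export
match_diary <- function(outings, diary, window_min = 30) {
  outings$accompaniment <- rep("unknown", nrow(outings))
  if (nrow(outings) == 0 || is.null(diary) || nrow(diary) == 0)
    return(outings)
  used <- rep(FALSE, nrow(diary))
  for (i in seq_len(nrow(outings))) {
    dt <- abs(as.numeric(diary$start) - as.numeric(outings$start[i]))
    dt[used] <- Inf
    j <- which.min(dt)
    if (dt[j] <= window_min * 60) {
      outings$accompaniment[i] <- diary$accompaniment[j]
      used[j] <- TRUE
    }
  }
  outings
}

#' Split outings by accompaniment label
#'
#' @param outings Outing tibble with an `accompaniment` column (see
#'   [match_diary()]).
#' @return A named list of tibbles: `alone`, `accompanied`, `unknown`;
#'   the three partitions are disjoint and exhaustive.
#' @export
split_by_accompaniment <- function(outings) {
  if (!"accompaniment" %in% names(outings))
    stop("outings lack an accompaniment column; run match_diary() first",
         call. = FALSE)
  list(alone = outings[outings$accompaniment == "alone", , drop = FALSE],
       accompanied = outings[outings$accompaniment == "accompanied", ,
                             drop = FALSE],
       unknown = outings[outings$accompaniment == "unknown", , drop = FALSE])
}
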