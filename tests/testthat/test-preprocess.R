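test_that("spike removal follows the maximum-speed threshold scan", {
  # a 500 m jump over 3 s is an apparent 600 km/h; the 200 km/h ceiling
  # allows only 166.7 m, so the fix must go
  x <- c(0, 5, 10, 510, 15, 20)
  tr <- trace_from_xy(x, rep(0, 6))
  res <- remove_spikes(tr, vmax_kmh = 200)
  expect_equal(res$removed, 4L)
  expect_equal(nrow(res$trace$fixes), 5)

  # two consecutive spikes: both measured against the last retained fix
  x2 <- c(0, 5, 505, 495, 10, 15)
  res2 <- remove_spikes(trace_from_xy(x2, rep(0, 6)), 200)
  expect_equal(res2$removed, c(3L, 4L))

  # a clean walking trace is untouched, and the scan is idempotent
  walk <- walk_out_and_back(300)
  res3 <- remove_spikes(walk, 200)
  expect_equal(res3$removed, integer(0))
  res4 <- remove_spikes(res2$trace, 200)
  expect_equal(res4$removed, integer(0))

  # traces of < 2 fixes pass through unchanged
  tiny <- trace_from_xy(0, 0)
  expect_equal(remove_spikes(tiny, 200)$removed, integer(0))
})

test_that("day cleaning drops only days without outdoor navigation", {
  t0 <- as.POSIXct("2023-05-01 10:00:00", tz = "UTC")
  day <- 86400
  mk <- function(x, t) {
    ll <- aeq_unproject(x, rep(0, length(x)), HOME[1], HOME[2])
    tibble::tibble(timestamp = t, lat = ll[, "lat"], lon = ll[, "lon"])
  }
  fixes <- dplyr::bind_rows(
    mk(c(0, 100, 200, 0), t0 + c(0, 60, 120, 180)),         # day 1: outing
    mk(c(0, 10, 20, 5), t0 + day + c(0, 60, 120, 180)),     # day 2: at home
    mk(c(0, 500, 900, 10), t0 + 2 * day + c(0, 60, 120, 180))) # day 3: outing
  tr <- gps_trace("T01", fixes, interval_s = 3)
  res <- clean_days(tr, HOME, home_radius_m = 30)
  expect_equal(res$removed_days, "2023-05-02")
  expect_equal(length(res$recorded_days), 2)
  expect_equal(nrow(res$trace$fixes), 8)
  expect_false(res$empty)

  # a trace that never leaves home is emptied and flagged
  stay <- gps_trace("T02", mk(c(0, 5, 10, 15), t0 + c(0, 60, 120, 180)))
  res2 <- clean_days(stay, HOME)
  expect_true(res2$empty)
  expect_equal(nrow(res2$trace$fixes), 0)

  # a trace with an outing every day is unchanged
  res3 <- clean_days(tr, HOME)
  expect_equal(nrow(res3$trace$fixes), 8)
})

test_that("window classification applies the mean/max speed thresholds", {
  # three windows engineered to hit each mode with defaults (1, 7, 12 km/h)
  sp <- c(0.3, 0.3, 0.8,   4.2, 4.2, 6.0,   38, 38, 55)
  tr <- trace_from_xy(cumsum(c(0, rep(3, 8))), rep(0, 9), speed_kmh = sp)
  wc <- window_and_classify(tr)
  expect_equal(nrow(wc$windows), 3)
  expect_equal(wc$windows$mode, c("stationary", "by_foot", "in_vehicle"))
  expect_true(all(wc$windows$mean_speed <= wc$windows$max_speed))
  # every fix maps to exactly one window
  expect_equal(sort(unique(wc$fix_window)), 1:3)
  expect_equal(length(wc$fix_window), 9)

  # 5 s interval uses 2-fix (10 s) windows
  tr5 <- trace_from_xy(cumsum(c(0, rep(6, 5))), rep(0, 6), interval_s = 5,
                       speed_kmh = rep(5, 6))
  wc5 <- window_and_classify(tr5)
  expect_equal(wc5$windows$n_fixes, c(2L, 2L, 2L))

  # speeds recomputed from positions when the device field is absent
  walk <- walk_out_and_back(100, speed_kmh = 4.5)
  walk$fixes$speed_kmh <- NULL
  wcw <- window_and_classify(walk)
  expect_true(all(wcw$windows$mode == "by_foot"))
  expect_equal(mean(wcw$windows$mean_speed), 4.5, tolerance = 0.05)

  # windows split at recording gaps
  tg <- trace_from_xy(c(0, 4, 8, 12, 16, 20), rep(0, 6),
                      speed_kmh = rep(4.5, 6))
  tg$fixes$timestamp <- tg$fixes$timestamp + c(0, 0, 0, 600, 600, 600)
  wcg <- window_and_classify(tg)
  expect_equal(nrow(wcg$windows), 2)
  expect_equal(wcg$windows$n_fixes, c(3L, 3L))
})

test_that("planted spikes are fully removed and genuine fixes survive", {
  spec <- cohort_spec(tracking_days = 7, spike_rate_per_1000 = 2)
  p <- generate_participant(spec, "control", HOME, 3L, "S01", 404)
  pre <- preprocess_trace(p$trace, HOME, pipeline_config())
  planted <- p$truth$spike_indices
  expect_gt(length(planted), 0)
  # every planted spike surviving day-cleaning is removed by the scan
  surviving <- which(!seq_len(nrow(p$trace$fixes)) %in% pre$kept_rows)
  expect_true(all(planted %in% surviving))
  # fewer than 1% of genuine fixes are lost
  genuine <- setdiff(seq_len(nrow(p$trace$fixes)), planted)
  lost <- setdiff(genuine, pre$kept_rows)
  # exclude fixes lost to day-cleaning, which is not the spike filter
  cl <- clean_days(p$trace, HOME, 30)
  lost_to_spikes <- intersect(lost, cl$kept_rows)
  expect_lt(length(lost_to_spikes) / length(genuine), 0.01)
})

test_that("window modes match planted modes on noise-free traces", {
  spec <- cohort_spec(tracking_days = 5, gps_sigma_m = 0,
                      spike_rate_per_1000 = 0)
  p <- generate_participant(spec, "control", HOME, 3L, "S02", 405)
  pre <- preprocess_trace(p$trace, HOME, pipeline_config())
  truth_mode <- p$truth$fix_mode[pre$kept_rows]
  got_mode <- pre$trace$fixes$mode
  ok <- !is.na(got_mode)
  acc <- mean(truth_mode[ok] == got_mode[ok])
  expect_gte(acc, 0.95)
})
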