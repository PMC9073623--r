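test_that("environment kinds have the promised geometry and are deterministic", {
  s1 <- generate_environment("single_street", 800, 0, seed = 1)
  expect_equal(nrow(s1$edges), 1)
  g <- generate_environment("grid", 400, 10, seed = 2, spacing_m = 200)
  expect_equal(nrow(g$nodes), 9) # 3x3
  deg <- node_degree(g)
  expect_equal(unname(deg[["n2_2"]]), 4L) # interior node degree 4
  st <- generate_environment("star", 800, 0, seed = 3)
  expect_equal(nrow(st$edges), 36)
  # equal ray lengths at 10-degree spacing
  ctr <- st$nodes[st$nodes$id == "c", ]
  lens <- haversine_m(st$nodes$lat[-1], st$nodes$lon[-1], ctr$lat, ctr$lon)
  expect_equal(max(lens) - min(lens), 0, tolerance = 1e-6)
  expect_error(generate_environment("hexagons", 800, 0), "arg")
  # determinism
  a <- generate_environment("irregular", 900, 25, seed = 9)
  b <- generate_environment("irregular", 900, 25, seed = 9)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$landmarks, b$landmarks)
})

test_that("zero-rate participants stay near home; truth has no outings", {
  zero <- cohort_spec(
    tracking_days = 3,
    conditions = list(control = list(all = cond_params(0, 0, 1, 0.5, 0, 5, 2))),
    stroll_rate_per_day = 0, spike_rate_per_1000 = 0)
  p <- generate_participant(zero, "control", HOME, 3L, "Z01", 5)
  expect_equal(nrow(p$truth$outings), 0)
  expect_gt(nrow(p$trace$fixes), 0) # daily heartbeat blocks
  d <- haversine_m(p$trace$fixes$lat, p$trace$fixes$lon, HOME[1], HOME[2])
  expect_lt(max(d), 60) # within noise of home
})

test_that("noise-free fixes lie exactly on the planted path", {
  spec <- cohort_spec(tracking_days = 2, gps_sigma_m = 0,
                      spike_rate_per_1000 = 0, stroll_rate_per_day = 0)
  p <- generate_participant(spec, "control", HOME, 3L, "N01", 6)
  # recovered per-outing path length equals planted within 1%
  pre <- preprocess_trace(p$trace, HOME, pipeline_config())
  outs <- detect_outings(pre$trace, HOME)
  tru <- p$truth$outings[!p$truth$outings$is_stroll, ]
  expect_equal(nrow(outs), nrow(tru))
  expect_equal(outs$path_length_m / 1000, tru$path_km, tolerance = 0.01)
})

test_that("planted spikes are recorded and displaced by at least the minimum", {
  spec <- cohort_spec(tracking_days = 4, spike_rate_per_1000 = 3)
  p <- generate_participant(spec, "control", HOME, 3L, "K01", 8)
  idx <- p$truth$spike_indices
  expect_gt(length(idx), 0)
  # rebuild the noise-free planned positions via a noiseless, spike-free
  # twin of the same seed (the planted outing plan precedes the noise and
  # spike draws in the generator, so the fix grid is identical)
  p0 <- generate_participant(
    cohort_spec(tracking_days = 4, spike_rate_per_1000 = 0, gps_sigma_m = 0),
    "control", HOME, 3L, "K01", 8)
  stopifnot(nrow(p0$trace$fixes) == nrow(p$trace$fixes))
  d <- haversine_m(p$trace$fixes$lat[idx], p$trace$fixes$lon[idx],
                   p0$trace$fixes$lat[idx], p0$trace$fixes$lon[idx])
  expect_true(all(d >= 300 - 1))
  expect_true(all(d <= 1000 + 1))
})

test_that("truth covers every emitted fix with exactly one mode", {
  p <- generate_participant(cohort_spec(tracking_days = 2), "patient",
                            HOME, 5L, "M01", 12)
  expect_equal(length(p$truth$fix_mode), nrow(p$trace$fixes))
  expect_true(all(p$truth$fix_mode %in%
                  c("stationary", "by_foot", "in_vehicle")))
})

test_that("planted outing counts converge to the Poisson rates", {
  # law of large numbers over many participants, within 3 Monte-Carlo SEs
  spec <- cohort_spec(tracking_days = 14, rate_factor_cv = 1e-3,
                      stroll_rate_per_day = 0)
  lam <- with(spec$conditions$control$all, rate_day + rate_night)
  n_p <- 12
  counts <- vapply(seq_len(n_p), function(i) {
    p <- generate_participant(spec, "control", HOME, 3L,
                              sprintf("L%02d", i), 3000 + i)
    sum(!p$truth$outings$is_stroll)
  }, 0L)
  days <- 14 * n_p
  se <- sqrt(lam / days)
  expect_lt(abs(sum(counts) / days - lam), 3 * se)
})

test_that("cohorts have the configured sizes, splits and determinism", {
  spec <- cohort_spec(n_control = 4, n_patient = 3, tracking_days = 2)
  c1 <- generate_cohort(spec, seed = 21)
  expect_equal(sum(c1$participants$group == "control"), 4)
  expect_equal(sum(c1$participants$group == "patient"), 3)
  expect_true(all(c1$participants$interval_s %in% c(3L, 5L)))
  c2 <- generate_cohort(spec, seed = 21)
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$traces[["P01"]]$fixes, c2$traces[["P01"]]$fixes)
  expect_identical(c1$truths[["C02"]]$outings, c2$truths[["C02"]]$outings)
  # patient diaries label outings with their planted condition
  d <- c1$diaries[["P01"]]
  if (nrow(d)) expect_true(all(d$accompaniment %in% c("alone", "accompanied")))
  # controls carry empty diaries
  expect_equal(nrow(c1$diaries[["C01"]]), 0)
})

test_that("a home outside the environment extent is rejected", {
  spec <- cohort_spec(tracking_days = 1)
  env <- generate_environment("grid", 1000, 5, seed = 2)
  far <- aeq_unproject(5000, 5000, env$center[1], env$center[2])
  expect_error(generate_participant(spec, "control",
                                    c(far[1, "lat"], far[1, "lon"]),
                                    3L, "X01", 1, env = env),
               "extent")
})

test_that("cohort round-trips through the on-disk dialects", {
  spec <- cohort_spec(n_control = 2, n_patient = 1, tracking_days = 2)
  coh <- generate_cohort(spec, seed = 33)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$participants), 3)
  expect_equal(back$traces[["C01"]]$fixes$lat, coh$traces[["C01"]]$fixes$lat,
               tolerance = 1e-8)
  expect_equal(nrow(back$env$landmarks), nrow(coh$env$landmarks))
  expect_equal(nrow(back$diaries[["P01"]]), nrow(coh$diaries[["P01"]]))
})
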