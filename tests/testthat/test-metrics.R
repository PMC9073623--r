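test_that("outing rates are counts over recorded days", {
  outs <- tibble::tibble(band = c(rep("day", 10), rep("night", 4)))
  r <- outing_rates(outs, 14)
  expect_equal(r$total, 1.0)
  expect_equal(r$day, 10 / 14)
  expect_equal(r$night, 4 / 14)
  expect_equal(outing_rates(outs[0, ], 14)$total, 0)
  expect_error(outing_rates(outs, 0), "recorded_days")
})

test_that("moving time sums non-stationary window fixes; gaps add nothing", {
  # 30 min by foot + 10 min stationary at 3 s sampling
  fixes <- tibble::tibble(mode = c(rep("by_foot", 600), rep("stationary", 200)))
  expect_equal(moving_time(fixes, 3), 0.5)
  expect_equal(moving_time(tibble::tibble(mode = rep("stationary", 50)), 3), 0)
  # a 20-min recording gap leaves no fixes, hence contributes 0 h
  expect_equal(moving_time(fixes[1:600, ], 3), 0.5)
})

test_that("outing distances match closed forms on planted lines", {
  # straight 1000 m line walked east, all by foot
  n <- 101
  x <- seq(0, 1000, length.out = n)
  ll <- aeq_unproject(x, rep(0, n), HOME[1], HOME[2])
  f <- tibble::tibble(lat = ll[, "lat"], lon = ll[, "lon"],
                      mode = "by_foot")
  d <- outing_distances(f, HOME)
  expect_equal(d$total_m, 1000, tolerance = 1e-3)
  expect_equal(d$walking_m, 1000, tolerance = 1e-3)
  expect_equal(d$mean_from_home_m, mean(x), tolerance = 0.1)

  # all-vehicle outing contributes no walking distance
  f$mode <- "in_vehicle"
  expect_equal(outing_distances(f, HOME)$walking_m, 0)

  # circle of radius r centred on home: mean distance from home is r
  th <- seq(0, 2 * pi, length.out = 200)
  llc <- aeq_unproject(500 * cos(th), 500 * sin(th), HOME[1], HOME[2])
  fc <- tibble::tibble(lat = llc[, "lat"], lon = llc[, "lon"],
                       mode = "by_foot")
  expect_equal(outing_distances(fc, HOME)$mean_from_home_m, 500,
               tolerance = 0.5)

  # walking distance can never exceed total
  set.seed(9)
  for (k in 1:20) {
    m <- rand_traj(30, 1e-4)
    fr <- tibble::tibble(lat = m[, 1], lon = m[, 2],
                         mode = sample(c("by_foot", "in_vehicle",
                                         "stationary"), 30, TRUE))
    dd <- outing_distances(fr, HOME)
    expect_lte(dd$walking_m, dd$total_m + 1e-9)
  }
})

test_that("discrete Frechet matches the identity and single-pair cases", {
  m <- rand_traj(20, 1e-3)
  expect_equal(discrete_frechet(m, m), 0)
  p <- matrix(c(52.6, 1.30), 1)
  q <- matrix(c(52.6, 1.3005), 1)
  d <- hav_oracle(p[1, ], q[1, ])
  expect_equal(discrete_frechet(p, q), d, tolerance = 1e-9)
  expect_error(discrete_frechet(m[0, , drop = FALSE], m), "empty")
})

test_that("discrete Frechet equals brute-force coupling enumeration", {
  set.seed(42)
  for (k in 1:60) {
    a <- rand_traj(sample(1:8, 1))
    b <- rand_traj(sample(1:8, 1))
    expect_equal(discrete_frechet(a, b), dfd_brute(a, b, hav_oracle),
                 tolerance = 1e-9)
  }
})

test_that("discrete Frechet is symmetric and bounded below by endpoints", {
  set.seed(7)
  for (k in 1:40) {
    a <- rand_traj(sample(2:12, 1))
    b <- rand_traj(sample(2:12, 1))
    d <- discrete_frechet(a, b)
    expect_equal(d, discrete_frechet(b, a))
    lb <- max(hav_oracle(a[1, ], b[1, ]),
              hav_oracle(a[nrow(a), ], b[nrow(b), ]))
    expect_gte(d, lb - 1e-9)
    # directed Hausdorff lower bound: every point of a must be matched
    haus <- max(apply(a, 1, function(p)
      min(apply(b, 1, function(q) hav_oracle(p, q)))))
    expect_gte(d, haus - 1e-9)
  }
})

test_that("degree-based Frechet convention works on raw coordinates", {
  a <- cbind(c(0, 1), c(0, 0))
  b <- cbind(c(0, 1), c(3, 3))
  expect_equal(discrete_frechet(a, b, units = "degrees"), 3)
})

test_that("trajectory similarity averages all unordered outing pairs", {
  # three trajectories engineered to have known pairwise distances
  base <- cbind(rep(52.6, 5), seq(1.30, 1.31, length.out = 5))
  shift <- function(dm) {
    ll <- aeq_unproject(rep(0, 5), rep(dm, 5), 52.6, 1.30)
    cbind(ll[, "lat"], base[, 2])
  }
  t1 <- base; t2 <- shift(100); t3 <- shift(300)
  d12 <- discrete_frechet(t1, t2); d13 <- discrete_frechet(t1, t3)
  d23 <- discrete_frechet(t2, t3)
  fx <- function(m) tibble::tibble(lat = m[, 1], lon = m[, 2])
  got <- trajectory_similarity(list(fx(t1), fx(t2), fx(t3)))
  expect_equal(got, mean(c(d12, d13, d23)), tolerance = 1e-5)
  # identical outings: zero
  expect_equal(trajectory_similarity(list(fx(t1), fx(t1), fx(t1))), 0)
  # fewer than two outings: undefined
  expect_true(is.na(trajectory_similarity(list(fx(t1)))))
  # downsampling changes little on dense trajectories
  set.seed(5)
  dense1 <- rand_traj(800, 1e-4); dense2 <- rand_traj(900, 1e-4)
  full <- discrete_frechet(dense1, dense2)
  ds <- trajectory_similarity(list(fx(dense1), fx(dense2)), max_points = 300)
  expect_equal(ds, full, tolerance = 0.05 * full + 20)
})

test_that("the eight-variable profile matches a hand-computed fixture", {
  t0 <- as.POSIXct("2023-05-01 10:00:00", tz = "UTC")
  step <- 4.5 / 3.6 * 3
  out <- seq(0, 400, by = step)
  mk_outing <- function(start, x) {
    ll <- aeq_unproject(x, rep(0, length(x)), HOME[1], HOME[2])
    tibble::tibble(timestamp = start + seq_along(x) * 3,
                   lat = ll[, "lat"], lon = ll[, "lon"], mode = "by_foot")
  }
  f1 <- mk_outing(t0, c(out, rev(out)))
  f2 <- mk_outing(t0 + 7 * 3600, c(out, out[length(out)] + out / 2,
                                   rev(out[length(out)] + out / 2), rev(out)))
  outs <- tibble::tibble(
    start = c(f1$timestamp[1], f2$timestamp[1]),
    end = c(f1$timestamp[nrow(f1)], f2$timestamp[nrow(f2)]),
    band = c("day", "day"),
    fixes = list(f1, f2))
  prof <- compute_profile(outs, 2, HOME, 3)
  expect_equal(prof$outings_per_day, 1.0)
  expect_equal(prof$day_outings_per_day, 1.0)
  expect_equal(prof$night_outings_per_day, 0.0)
  exp_total <- (path_length_m(f1$lat, f1$lon) +
                path_length_m(f2$lat, f2$lon)) / 2000
  expect_equal(prof$total_km_per_outing, exp_total, tolerance = 1e-6)
  expect_equal(prof$walking_km_per_outing, exp_total, tolerance = 1e-6)
  expect_equal(prof$moving_hours_per_outing,
               (nrow(f1) + nrow(f2)) / 2 * 3 / 3600)
  expect_equal(prof$mean_dfd,
               discrete_frechet(cbind(f1$lat, f1$lon),
                                cbind(f2$lat, f2$lon)), tolerance = 1e-9)

  # zero-outing participant: rates 0, per-outing fields missing
  p0 <- compute_profile(outs[0, ], 5, HOME, 3)
  expect_equal(p0$outings_per_day, 0)
  expect_true(is.na(p0$total_km_per_outing))
  expect_true(is.na(p0$mean_dfd))
})

test_that("day and night rates always sum to the total rate", {
  set.seed(31)
  for (k in 1:10) {
    n <- sample(0:20, 1)
    outs <- tibble::tibble(band = sample(c("day", "night"), n, TRUE))
    r <- outing_rates(outs, 14)
    expect_equal(r$day + r$night, r$total, tolerance = 1e-12)
  }
})
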