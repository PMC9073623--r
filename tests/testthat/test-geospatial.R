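test_that("buffer areas match closed forms", {
  # single point: disc of area pi r^2
  b1 <- build_buffer(tibble::tibble(lat = HOME[1], lon = HOME[2]), 80)
  expect_equal(buffer_area(b1), pi * 80^2, tolerance = 0.005 * pi * 80^2)
  # straight 1000 m segment, radius 30: stadium = 2 r L + pi r^2
  ll <- aeq_unproject(c(0, 1000), c(0, 0), HOME[1], HOME[2])
  b2 <- build_buffer(tibble::tibble(lat = ll[, "lat"], lon = ll[, "lon"]), 30)
  exp_area <- 1000 * 60 + pi * 30^2
  expect_equal(buffer_area(b2), exp_area, tolerance = 0.005 * exp_area)
  expect_error(build_buffer(tibble::tibble(lat = 52, lon = 1), -5), "radius")
})

test_that("every trajectory point lies inside its own buffer", {
  set.seed(21)
  for (k in 1:10) {
    m <- rand_traj(40, 2e-4)
    b <- build_buffer(m, 30)
    expect_true(all(buffer_contains(b, m[, 1], m[, 2])))
  }
})

test_that("buffer membership equals the brute-force distance oracle", {
  set.seed(77)
  for (k in 1:50) {
    n <- sample(2:30, 1)
    xy <- cbind(cumsum(runif(n, -80, 80)), cumsum(runif(n, -80, 80)))
    ll <- aeq_unproject(xy[, 1], xy[, 2], HOME[1], HOME[2])
    b <- build_buffer(tibble::tibble(lat = ll[, "lat"], lon = ll[, "lon"]),
                      runif(1, 20, 100))
    pts <- cbind(runif(60, min(xy[, 1]) - 150, max(xy[, 1]) + 150),
                 runif(60, min(xy[, 2]) - 150, max(xy[, 2]) + 150))
    pll <- aeq_unproject(pts[, 1], pts[, 2], HOME[1], HOME[2])
    got <- buffer_contains(b, pll[, "lat"], pll[, "lon"])
    # oracle works in the buffer's own projected frame
    pxy <- aeq_project(pll[, "lat"], pll[, "lon"], b$lat0, b$lon0)
    want <- vapply(seq_len(nrow(pts)), function(i)
      in_buffer_oracle(pxy[i, 1], pxy[i, 2], b$xy[, 1], b$xy[, 2],
                       b$radius_m), TRUE)
    expect_equal(got, want)
  }
})

test_that("landmark counting respects the 80 m radius exactly", {
  # straight walking path along x; landmarks planted at 79 m and 81 m
  ll <- aeq_unproject(seq(0, 500, by = 10), rep(0, 51), HOME[1], HOME[2])
  traj <- tibble::tibble(lat = ll[, "lat"], lon = ll[, "lon"])
  b <- build_buffer(traj, 80)
  lm <- aeq_unproject(c(250, 250), c(79, 81), HOME[1], HOME[2])
  lms <- tibble::tibble(lat = lm[, "lat"], lon = lm[, "lon"])
  expect_equal(landmark_density(b, lms, 2), 0.5) # 1 landmark / 2 km
  expect_true(is.na(landmark_density(b, lms, 0)))
  # arithmetic: 10 landmarks inside over 2 km -> 5 per km
  lm10 <- aeq_unproject(seq(50, 455, length.out = 10), rep(0, 10),
                        HOME[1], HOME[2])
  expect_equal(landmark_density(b, tibble::tibble(lat = lm10[, "lat"],
                                                  lon = lm10[, "lon"]), 2), 5)
})

test_that("intersection stats count degree >= 3 nodes in the 30 m buffer", {
  env <- generate_environment("grid", extent_m = 400, landmark_count = 0,
                              seed = 5, spacing_m = 200)
  deg <- node_degree(env)
  expect_equal(max(deg), 4L) # interior node of a 3x3 grid
  expect_equal(sum(deg >= 3), 5L) # 1 centre + 4 edge-midpoints
  # a path through the central 4-way crossing
  centre <- env$nodes[which.max(deg), ]
  ll <- aeq_unproject(seq(-20, 20, by = 5), rep(0, 9), centre$lat, centre$lon)
  b <- build_buffer(tibble::tibble(lat = ll[, "lat"], lon = ll[, "lon"]), 30)
  st <- intersection_stats(b, env, 1.5)
  expect_equal(st$intersection_density, 1 / 1.5)
  expect_equal(st$mean_complexity, 4)
  # a path far from any junction
  far <- aeq_unproject(c(5000, 5100), c(5000, 5000), HOME[1], HOME[2])
  b2 <- build_buffer(tibble::tibble(lat = far[, "lat"], lon = far[, "lon"]),
                     30)
  st2 <- intersection_stats(b2, env, 1.5)
  expect_equal(st2$intersection_density, 0)
  expect_true(is.na(st2$mean_complexity))
})

test_that("intersection counts equal the node-in-buffer oracle on random nets", {
  set.seed(13)
  for (k in 1:20) {
    env <- generate_environment("irregular", extent_m = 1000,
                                landmark_count = 30, seed = k,
                                spacing_m = 250)
    m <- rand_traj(30, 3e-4)
    b <- build_buffer(m, 30)
    blm <- build_buffer(m, 80)
    # oracle: project and check distances directly
    oracle_in <- function(lat, lon, buf) {
      xy <- aeq_project(lat, lon, buf$lat0, buf$lon0)
      vapply(seq_along(lat), function(i)
        in_buffer_oracle(xy[i, 1], xy[i, 2], buf$xy[, 1], buf$xy[, 2],
                         buf$radius_m), TRUE)
    }
    deg <- node_degree(env)
    inter <- env$nodes[deg[env$nodes$id] >= 3, ]
    st <- intersection_stats(b, env, 1)
    expect_equal(st$intersection_density,
                 sum(oracle_in(inter$lat, inter$lon, b)))
    expect_equal(landmark_density(blm, env$landmarks, 1),
                 sum(oracle_in(env$landmarks$lat, env$landmarks$lon, blm)))
  }
})

test_that("orientation entropy hits the closed forms", {
  centre <- tibble::tibble(lat = 52.628, lon = 1.299)
  b <- build_buffer(centre, 2030)
  single <- generate_environment("single_street", extent_m = 800,
                                 landmark_count = 0, seed = 1)
  expect_equal(orientation_entropy(b, single), log(2), tolerance = 1e-9)
  grid <- generate_environment("grid", extent_m = 800, landmark_count = 0,
                               seed = 1, spacing_m = 200)
  expect_equal(orientation_entropy(b, grid), log(4), tolerance = 1e-9)
  star <- generate_environment("star", extent_m = 800, landmark_count = 0,
                               seed = 1)
  expect_equal(orientation_entropy(b, star), log(36), tolerance = 1e-9)
  # no roads within the buffer: undefined
  bfar <- build_buffer(tibble::tibble(lat = 53.5, lon = 1.299), 2030)
  expect_true(is.na(orientation_entropy(bfar, grid)))
})

test_that("orientation entropy is invariant to bin-width rotations and edge reversal", {
  b <- build_buffer(tibble::tibble(lat = 52.628, lon = 1.299), 2030)
  env <- generate_environment("irregular", extent_m = 900, landmark_count = 0,
                              seed = 8, spacing_m = 300)
  h0 <- orientation_entropy(b, env)
  # reverse every edge
  env_rev <- environment_layer(env$landmarks, env$nodes,
                               tibble::tibble(from = env$edges$to,
                                              to = env$edges$from))
  expect_equal(orientation_entropy(b, env_rev), h0, tolerance = 1e-12)
  # rotate the whole network by exactly one bin width (10 degrees)
  ctr <- env$center
  xy <- aeq_project(env$nodes$lat, env$nodes$lon, ctr[1], ctr[2])
  th <- 10 * pi / 180
  rot <- cbind(xy[, 1] * cos(th) - xy[, 2] * sin(th),
               xy[, 1] * sin(th) + xy[, 2] * cos(th))
  rll <- aeq_unproject(rot[, 1], rot[, 2], ctr[1], ctr[2])
  env_rot <- environment_layer(env$landmarks,
                               tibble::tibble(id = env$nodes$id,
                                              lat = rll[, "lat"],
                                              lon = rll[, "lon"]),
                               env$edges)
  expect_equal(orientation_entropy(b, env_rot), h0, tolerance = 1e-6)
})

test_that("entropy grows as new orientations join a single street", {
  b <- build_buffer(tibble::tibble(lat = 52.628, lon = 1.299), 2030)
  # equal-length streets added one orientation at a time
  mk_env <- function(bearings) {
    ang <- bearings * pi / 180
    n <- length(ang)
    nodes <- tibble::tibble(id = c("c", paste0("s", seq_len(n))),
                            x = c(0, 400 * sin(ang)), y = c(0, 400 * cos(ang)))
    ll <- aeq_unproject(nodes$x, nodes$y, 52.628, 1.299)
    environment_layer(tibble::tibble(lat = numeric(), lon = numeric()),
                      tibble::tibble(id = nodes$id, lat = ll[, "lat"],
                                     lon = ll[, "lon"]),
                      tibble::tibble(from = "c", to = paste0("s", seq_len(n))))
  }
  hs <- vapply(list(c(0), c(0, 40), c(0, 40, 80), c(0, 40, 80, 120)),
               function(bb) orientation_entropy(b, mk_env(bb)), 0)
  expect_true(all(diff(hs) > -1e-12))
})
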