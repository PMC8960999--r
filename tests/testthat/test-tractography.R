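test_that("orientation sampling selects, perturbs and sign-aligns as specified", {
  f <- uniform_field(dir = c(0, 0, 1))
  centre <- c(0, 0, 0)  # world origin = grid centre
  # dispersion 0, aligned previous direction: the mean exactly
  expect_equal(sample_orientation(f, centre, c(0, 0, 1)), c(0, 0, 1))
  # anti-parallel previous direction: the negated mean
  expect_equal(sample_orientation(f, centre, c(0, 0, -1)), c(0, 0, -1))
  # no population above the floor -> NULL
  f_low <- uniform_field(frac = 0.03)
  expect_null(sample_orientation(f_low, centre, c(0, 0, 1)))
  # position outside the grid is an error
  expect_error(sample_orientation(f, c(100, 0, 0), NULL), "outside the grid")
})

test_that("best-aligned population wins among crossing fibres", {
  dims <- c(11L, 11L, 11L)
  grid <- volume_grid(dims, voxel_size = 1)
  dirs <- array(0, c(dims, 3L, 2L))
  dirs[, , , 1, 1] <- 1  # population A along +x
  dirs[, , , 2, 2] <- 1  # population B along +y
  frac <- array(0.4, c(dims, 2L))
  disp <- array(0, c(dims, 2L))
  f <- fibre_field(grid, dirs, frac, disp)
  # derived oracle: enumerate both candidates, pick max |dot|
  for (prev in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                    c(0.9, 0.1, 0) / sqrt(0.82))) {
    cands <- list(c(1, 0, 0), c(0, 1, 0))
    best <- cands[[which.max(vapply(cands, function(m)
      abs(sum(m * prev)), numeric(1)))]]
    if (sum(best * prev) < 0) best <- -best
    expect_equal(sample_orientation(f, c(0, 0, 0), prev), best)
  }
})

test_that("streamlines propagate bidirectionally and respect mask logic", {
  f <- uniform_field(dims = c(21L, 21L, 21L), dir = c(0, 0, 1))
  dims <- f$grid$dims
  # no masks: runs to both grid faces through the seed
  st <- propagate_streamline(c(0, 0, 0), f, params = tracking_params())
  expect_equal(st$status, "accepted")
  expect_setequal(st$stop_reasons, "grid_exit")
  expect_lt(min(st$points[, 3]), -9)
  expect_gt(max(st$points[, 3]), 9)
  # steps are step_size apart
  steps <- sqrt(rowSums(diff(st$points)^2))
  expect_equal(max(abs(steps - 0.5)), 0, tolerance = 1e-10)

  # waypoints on the fibre line -> accepted; off the line -> rejected_waypoint
  top <- voxel_box(dims, k = c(19L, 21L))
  bottom <- voxel_box(dims, k = c(1L, 3L))
  side <- voxel_box(dims, i = c(1L, 2L))
  st2 <- propagate_streamline(c(0, 0, 0), f,
                              masks = list(waypoints = list(top, bottom)))
  expect_equal(st2$status, "accepted")
  st3 <- propagate_streamline(c(0, 0, 0), f,
                              masks = list(waypoints = list(side)))
  expect_equal(st3$status, "rejected_waypoint")

  # exclusion on the line rejects regardless of waypoints
  st4 <- propagate_streamline(c(0, 0, 0), f,
                              masks = list(waypoints = list(top),
                                           exclusions = list(bottom)))
  expect_equal(st4$status, "rejected_exclusion")

  # termination mask stops the half-track inside it
  st5 <- propagate_streamline(c(0, 0, 0), f,
                              masks = list(termination = top))
  expect_true("termination_mask" %in% st5$stop_reasons)
  expect_lt(max(st5$points[, 3]), 9.6)  # never beyond the first mask voxel
})

test_that("a 90-degree bend falls below the 0.2 curvature threshold and rejects", {
  dims <- c(21L, 21L, 21L)
  grid <- volume_grid(dims, voxel_size = 1)
  dirs <- array(0, c(dims, 3L, 1L))
  dirs[, , 1:10, 3, 1] <- 1   # +z below the bend plane
  dirs[, , 11:21, 1, 1] <- 1  # +x above it: cos(90 deg) = 0 < 0.2
  f <- fibre_field(grid, dirs, array(0.5, c(dims, 1L)),
                   array(0, c(dims, 1L)))
  st <- propagate_streamline(c(0, 0, -5), f, params = tracking_params())
  expect_equal(st$status, "rejected_curvature")
  # a relaxed threshold of 0 admits the bend
  st2 <- propagate_streamline(c(0, 0, -5), f,
                              params = tracking_params(curvature_threshold = 0))
  expect_equal(st2$status, "accepted")
})

test_that("visitation maps are deterministic fractions of launched streamlines", {
  f <- uniform_field(dims = c(15L, 15L, 15L), dir = c(0, 0, 1))
  dims <- f$grid$dims
  seed_mask <- array(FALSE, dims); seed_mask[8, 8, 8] <- TRUE
  top <- voxel_box(dims, k = c(14L, 15L))
  set.seed(1)
  m <- track_seed_region(seed_mask, waypoints = list(top), field = f,
                         params = tracking_params(samples_per_voxel = 10))
  # deterministic field: every voxel on the unique path has value 1
  expect_equal(sort(unique(as.vector(m$data))), c(0, 1))
  expect_equal(sum(m$data[8, 8, ] == 1), 15)
  expect_equal(m$log$counts[["accepted"]], 10)

  # unreachable waypoint zeroes the map
  side <- voxel_box(dims, i = c(1L, 1L), j = c(1L, 1L))
  side[8, 8, ] <- FALSE
  set.seed(1)
  m0 <- track_seed_region(seed_mask, waypoints = list(side), field = f,
                          params = tracking_params(samples_per_voxel = 10))
  expect_true(all(m0$data == 0))

  expect_error(track_seed_region(array(FALSE, dims), waypoints = list(top),
                                 field = f), "seed mask is empty")

  # reproducibility under a fixed seed
  set.seed(7); a <- track_seed_region(seed_mask, list(top), field = f)
  set.seed(7); b <- track_seed_region(seed_mask, list(top), field = f)
  expect_identical(a$data, b$data)
})

test_that("acceptance fractions follow the binomial seed-population split", {
  # two populations at the seed voxel: +z reaches the waypoint, +x does not;
  # first-step selection is proportional to equal fractions, so accepted
  # fraction ~ Binomial(n, 1/2)
  dims <- c(15L, 15L, 15L)
  grid <- volume_grid(dims, voxel_size = 1)
  dirs <- array(0, c(dims, 3L, 2L))
  dirs[, , , 3, 1] <- 1
  dirs[, , , 1, 2] <- 1
  frac <- array(0, c(dims, 2L))
  frac[8, 8, , 1] <- 0.4            # +z column
  frac[, 8, 8, 2] <- 0.4            # +x row
  frac[8, 8, 8, ] <- 0.4            # seed voxel carries both
  f <- fibre_field(grid, dirs, frac, array(0, c(dims, 2L)))
  seed_mask <- array(FALSE, dims); seed_mask[8, 8, 8] <- TRUE
  top <- voxel_box(dims, k = c(14L, 15L))
  n <- 2000
  set.seed(3)
  m <- track_seed_region(seed_mask, waypoints = list(top), field = f,
                         params = tracking_params(samples_per_voxel = n))
  p_hat <- m$data[8, 8, 8]
  expect_lt(abs(p_hat - 0.5), 4 * sqrt(0.25 / n))
})

test_that("DTCp reconstruction normalises the summed maps to a unit maximum", {
  grid <- volume_grid(c(8L, 8L, 8L), voxel_size = 1)
  set.seed(2)
  a <- pico_map(array(stats::runif(512), c(8, 8, 8)), grid)
  b <- pico_map(array(stats::runif(512), c(8, 8, 8)), grid)
  d <- reconstruct_dtcp(a, b)
  expect_equal(max(d$data), 1)
  expect_equal(d$raw_max, max(a$data + b$data))
  expect_equal(d$data * d$raw_max, a$data + b$data)
  # A = B: output = A / max(A)
  d2 <- reconstruct_dtcp(a, a)
  expect_equal(d2$data, a$data / max(a$data))
  # zero maps pass through with a warning
  z <- pico_map(array(0, c(8, 8, 8)), grid)
  expect_warning(dz <- reconstruct_dtcp(z, z), "zero")
  expect_true(all(dz$data == 0))
  # scale invariance: c * raw maps leave the combined map unchanged
  for (cc in c(0.1, 3, 10)) {
    ac <- pico_map(a$data * cc, grid); bc <- pico_map(b$data * cc, grid)
    expect_equal(reconstruct_dtcp(ac, bc)$data, d$data)
  }
  # grid mismatch is an error
  g2 <- volume_grid(c(8L, 8L, 8L), voxel_size = 2)
  expect_error(reconstruct_dtcp(a, pico_map(array(1, c(8, 8, 8)), g2)),
               "different grids")
})

test_that("raising the curvature threshold never increases acceptances", {
  # deterministic 45-degree bend (cos = 0.707): thresholds sweep across it
  dims <- c(21L, 21L, 21L)
  grid <- volume_grid(dims, voxel_size = 1)
  dirs <- array(0, c(dims, 3L, 1L))
  dirs[, , 1:10, 3, 1] <- 1                       # +z below the bend
  dirs[, , 11:21, 1, 1] <- 1 / sqrt(2)            # 45 degrees above it
  dirs[, , 11:21, 3, 1] <- 1 / sqrt(2)
  f <- fibre_field(grid, dirs, array(0.5, c(dims, 1L)),
                   array(0, c(dims, 1L)))
  seed_mask <- array(FALSE, dims); seed_mask[11, 11, 3] <- TRUE
  counts <- vapply(c(0, 0.3, 0.6, 0.75, 0.9), function(ct) {
    set.seed(5)
    m <- track_seed_region(seed_mask, waypoints = list(),
                           field = f,
                           params = tracking_params(samples_per_voxel = 20,
                                                    curvature_threshold = ct))
    m$log$counts[["accepted"]]
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[[1]], 20)  # below cos(45) the bend is admitted
  expect_equal(counts[[5]], 0)   # above it every streamline is rejected
})
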