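test_that("quadrant assignment follows the half-open diagonal convention", {
  sp <- sphere_geometry(c(0, 0), 100)
  q <- assign_quadrants(sp, c(0, 1))  # vertical stripes
  # due north of center (y downward, north = -y) bisected by the stripes
  expect_equal(q(0, -200), "parallel")
  expect_equal(q(0, 200), "parallel")
  expect_equal(q(200, 0), "perpendicular")
  # exactly +45 degrees from the stripe direction is perpendicular (the
  # sector boundary belongs to its counter-clockwise neighbour), while the
  # -45 degree boundary stays parallel
  expect_equal(q(-200, 200), "perpendicular")
  expect_equal(q(200, 200), "parallel")
  # rotating the orientation by 90 degrees swaps every label
  q90 <- assign_quadrants(sp, c(1, 0))
  set.seed(1)
  ang <- runif(200, 0, 2 * pi)
  x <- 150 * cos(ang); y <- 150 * sin(ang)
  expect_true(all(q(x, y) != q90(x, y)))
  expect_error(assign_quadrants(sp, c(0, 0)), "nonzero")
})

test_that("a straight radial trace crosses each ring once, in its own quadrant", {
  sp <- sphere_geometry(c(0, 0), 100)
  tr <- data.frame(trace_id = 1, vertex_index = 1:2,
                   x_um = c(0, 0), y_um = c(-100, -155))
  prof <- sholl_quadrant_profile(tr, sp, ring_spacing = 10,
                                 stripe_orientation = c(0, 1))
  expect_equal(prof$ring_um, c(10, 20, 30, 40, 50))
  expect_equal(prof$crossings_parallel, rep(1L, 5))
  expect_equal(prof$crossings_perpendicular, rep(0L, 5))

  none <- sholl_quadrant_profile(tr[0, ], sp, stripe_orientation = c(0, 1))
  expect_equal(nrow(none), 0)

  inside <- data.frame(trace_id = 1, vertex_index = 1:3,
                       x_um = c(0, 10, 20), y_um = c(0, 5, 0))
  p2 <- sholl_quadrant_profile(inside, sp, stripe_orientation = c(0, 1),
                               max_ring_um = 30)
  expect_equal(sum(p2$crossings_total), 0)
  expect_equal(attr(p2, "n_inside"), 1L)
})

test_that("sholl counts match the brute-force intersection oracle", {
  for (seed in c(3, 17)) {
    traces <- random_trace_set(seed, n_traces = 50)
    sp <- attr(traces, "sphere")
    prof <- sholl_quadrant_profile(traces, sp, ring_spacing = 10,
                                   stripe_orientation = c(0, 1))
    orc <- oracle_sholl(traces, sp, 10, c(0, 1), nrow(prof))
    expect_identical(prof$crossings_parallel, orc$par)
    expect_identical(prof$crossings_perpendicular, orc$per)
  }
})

test_that("sholl profile is invariant under rigid rotation and conserves totals", {
  traces <- random_trace_set(7, n_traces = 20)
  sp <- attr(traces, "sphere")
  prof <- sholl_quadrant_profile(traces, sp, stripe_orientation = c(0, 1))
  expect_equal(prof$crossings_parallel + prof$crossings_perpendicular,
               prof$crossings_total)

  th <- 0.7  # rotate everything together
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- traces
  xy <- as.matrix(traces[, c("x_um", "y_um")]) %*% t(R)
  rot$x_um <- xy[, 1]; rot$y_um <- xy[, 2]
  prof_rot <- sholl_quadrant_profile(rot, sp,
                                     stripe_orientation = as.numeric(R %*% c(0, 1)))
  expect_equal(prof_rot$crossings_parallel, prof$crossings_parallel)
  expect_equal(prof_rot$crossings_perpendicular, prof$crossings_perpendicular)
})

test_that("segmentation recovers rendered structures and handles degenerate input", {
  st <- generate_stripe_pattern(50, 300, scale = 2)
  sc <- scene_params(n_neurites = 20, sphere_radius = 120, max_length = 200,
                     seed = 8)
  traces <- simulate_neurite_traces(sc, st)
  scn <- render_scene(traces, st, psf_sigma = 0, background = 0,
                      noise_sd = 0)
  mask <- segment_neurites(scn$factin, scale = 2, threshold_method = "fixed",
                           fixed_value = 0.5)
  raster_area <- sum(scn$raster)
  expect_lt(abs(sum(mask) - raster_area) / raster_area, 0.1)

  expect_warning(empty <- segment_neurites(matrix(0, 10, 10)), "variance")
  expect_false(any(empty))
  high <- segment_neurites(scn$factin, scale = 2, threshold_method = "fixed",
                           fixed_value = max(scn$factin) + 1)
  expect_false(any(high))
})

test_that("substratum preference is exact on constructed masks", {
  st <- generate_stripe_pattern(50, 400, scale = 2)
  sp <- sphere_geometry(c(400, 400), 100)
  full <- matrix(TRUE, 400, 400)
  pref <- substratum_preference(full, st, sp)
  expect_true(pref$valid)
  expect_equal(pref$normalized_preference, 1.0)

  ln_only <- matrix(!st$label, 400, 400)
  pref0 <- substratum_preference(ln_only, st, sp)
  expect_equal(pref0$normalized_preference, 0.0)

  # empty laminin coverage flags the result instead of dividing by zero
  cue_only <- matrix(st$label, 400, 400)
  prefc <- substratum_preference(cue_only, st, sp)
  expect_false(prefc$valid)
  expect_true(is.na(prefc$normalized_preference))
})

test_that("preference swaps to its reciprocal when cue and laminin labels swap", {
  st <- generate_stripe_pattern(50, 400, scale = 2)
  sp <- sphere_geometry(c(400, 400), 100)
  traces <- simulate_neurite_traces(
    scene_params(n_neurites = 60, sphere_radius = 100, seed = 2,
                 avoidance_beta = 1), st)
  mask <- rasterize_traces(traces, dim(st$label), st$scale)
  p1 <- substratum_preference(mask, st, sp)
  swapped <- st
  swapped$label <- !st$label
  swapped$stripe_width <- NULL  # force pixel-map lookup of swapped labels
  p2 <- substratum_preference(mask, swapped, sp)
  expect_equal(p2$normalized_preference, 1 / p1$normalized_preference,
               tolerance = 1e-12)
})
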