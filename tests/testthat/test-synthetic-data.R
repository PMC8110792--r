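test_that("stripe pattern lanes alternate with equal width and half-open bounds", {
  p <- generate_stripe_pattern(50, 1000, scale = 1)
  expect_equal(mean(p$label), 0.5)
  runs <- rle(p$label[, 1])
  expect_true(all(runs$lengths == 50))
  expect_equal(length(runs$lengths), 20)

  # single lane when stripe width spans the image; fraction by pixel count
  p1 <- generate_stripe_pattern(1000, c(1000, 10), scale = 1)
  expect_equal(sum(p1$label), 1000 * 10)

  ph <- generate_stripe_pattern(50, 1000, scale = 1,
                                orientation = "horizontal")
  expect_identical(ph$label, t(p$label))

  expect_error(generate_stripe_pattern(-5, 100), "stripe_width")
  expect_error(generate_stripe_pattern(50, 100, scale = 0), "scale")
})

test_that("stripe lookup is analytic and consistent off-canvas", {
  p <- generate_stripe_pattern(50, 100, scale = 1)
  expect_true(stripe_is_cue(p, 10, 5))
  expect_false(stripe_is_cue(p, 60, 5))
  # beyond the canvas the periodic formula still applies
  expect_true(stripe_is_cue(p, 210, -40))
  expect_false(stripe_is_cue(p, 260, 1e4))
})

test_that("trace simulation is seed-deterministic and map-independent at beta 0", {
  st <- generate_stripe_pattern(50, 600, scale = 2)
  sc <- scene_params(avoidance_beta = 0, n_neurites = 25, seed = 11)
  a <- simulate_neurite_traces(sc, st)
  b <- simulate_neurite_traces(sc, st)
  expect_identical(a, b)

  other <- generate_stripe_pattern(30, 600, scale = 2,
                                   orientation = "horizontal")
  c <- simulate_neurite_traces(sc, other)
  expect_identical(a$x_um, c$x_um)
  expect_identical(a$y_um, c$y_um)

  # traces start on the rim
  sp <- attr(a, "sphere")
  first <- a[a$vertex_index == 1, ]
  d <- sqrt((first$x_um - sp$center[1])^2 + (first$y_um - sp$center[2])^2)
  expect_equal(d, rep(sp$radius, nrow(first)), tolerance = 1e-10)

  expect_equal(nrow(simulate_neurite_traces(
    scene_params(n_neurites = 0), st)), 0)
})

test_that("strong avoidance keeps trace vertices off cue lanes beyond their first lane", {
  st <- generate_stripe_pattern(50, 600, scale = 2)
  frac_on_cue_after_exit <- function(beta) {
    hits <- 0L; tot <- 0L
    for (s in 1:10) {
      sc <- scene_params(avoidance_beta = beta, n_neurites = 20, seed = s)
      tr <- simulate_neurite_traces(sc, st)
      for (m in split_traces(tr)) {
        cue <- stripe_is_cue(st, m[, 1], m[, 2])
        lane <- floor(m[, 1] / st$stripe_width)
        after <- which(lane != lane[1])
        if (length(after)) {
          tot <- tot + length(after)
          hits <- hits + sum(cue[after])
        }
      }
    }
    hits / tot
  }
  f20 <- frac_on_cue_after_exit(20)
  f0 <- frac_on_cue_after_exit(0)
  expect_lt(f20, 0.01)
  expect_gt(f0, 0.3)
})

test_that("rendered scenes carry ground truth and preserve the cue fraction", {
  st <- generate_stripe_pattern(50, 300, scale = 2)
  sc <- scene_params(n_neurites = 15, sphere_radius = 120, max_length = 150,
                     seed = 4)
  traces <- simulate_neurite_traces(sc, st)
  scn <- render_scene(traces, st, psf_sigma = 0.5, background = 0,
                      noise_sd = 0)
  expect_equal(mean(scn$stripe > 0.5), mean(st$label))
  expect_identical(scn$traces, traces)

  # at any threshold in (0, peak) the mask skeleton stays within 1 px of
  # the rasterized ground truth
  raster <- scn$raster
  dist_to_raster <- EBImage::distmap(!raster)
  for (thr in c(0.2, 0.5, 0.8) * max(scn$factin)) {
    mask <- scn$factin > thr
    skel <- gconequant:::thin_mask(mask)
    expect_lte(max(dist_to_raster[skel]), sqrt(2))
  }

  # background only: nothing to detect
  blank <- render_scene(traces[0, ], st, background = 0.1, noise_sd = 0)
  expect_warning(m <- segment_neurites(blank$factin, scale = 2),
                 "zero variance")
  expect_false(any(m))
})

test_that("growth cone generator is seed-deterministic and label-faithful", {
  gp <- growth_cone_params(state = "spread", seed = 5)
  a <- simulate_growth_cone(gp)
  b <- simulate_growth_cone(gp)
  expect_identical(a$image, b$image)
  expect_identical(a$state, "spread")

  # constructed morphologies satisfy the collapse rule they are labelled with
  call_c <- score_growth_cone(simulate_growth_cone(
    growth_cone_params(state = "collapsed", noise_sd = 0, seed = 2)))
  expect_true(call_c$collapsed)
  call_s <- score_growth_cone(simulate_growth_cone(
    growth_cone_params(state = "spread", noise_sd = 0, seed = 2)))
  expect_false(call_s$collapsed)
})

test_that("track generator follows rate, retraction, and noise specification", {
  tr <- simulate_timelapse_track(track_params(true_rate = 12,
                                              frame_interval = 5,
                                              n_frames = 20,
                                              position_noise_sd = 0,
                                              seed = 1))
  expect_equal(diff(tr$x_um), rep(1, 19))
  expect_equal(tr$t_min, seq(0, 95, by = 5))

  tr2 <- simulate_timelapse_track(track_params(true_rate = 12,
                                               retraction_prob = 1,
                                               retraction_magnitude = 50,
                                               position_noise_sd = 0,
                                               n_frames = 10, seed = 1))
  expect_equal(diff(tr2$x_um), rep(1 - 50, 9))

  same <- simulate_timelapse_track(track_params(seed = 9))
  expect_identical(same, simulate_timelapse_track(track_params(seed = 9)))
})

test_that("FRET pair generator inverts exactly under the ideal estimator", {
  pair <- simulate_fret_pair(fret_params(true_efficiency = 0.2,
                                         bleach_fraction = 1,
                                         noise = "none"))
  r <- fret_efficiency(pair)
  expect_equal(r$efficiency, 0.2, tolerance = 1e-12)
  expect_true(r$valid)

  pair0 <- simulate_fret_pair(fret_params(true_efficiency = 0,
                                          noise = "none"))
  expect_equal(fret_efficiency(pair0)$efficiency, 0, tolerance = 1e-12)

  expect_identical(simulate_fret_pair(fret_params(seed = 3)),
                   simulate_fret_pair(fret_params(seed = 3)))
  expect_error(fret_params(true_efficiency = 1))
  expect_error(fret_params(bleach_fraction = 0))
})
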