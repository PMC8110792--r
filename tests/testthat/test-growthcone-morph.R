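test_that("factin mask keeps the largest filled component", {
  img <- matrix(0, 100, 100)
  img[10:40, 10:40] <- 1    # large blob with a hole
  img[20:25, 20:25] <- 0
  img[70:75, 70:75] <- 1    # small distractor blob
  mask <- make_factin_mask(img, scale = 1, threshold_method = "fixed",
                           fixed_value = 0.5)
  expect_true(all(mask[20:25, 20:25]))   # hole filled
  expect_false(any(mask[70:75, 70:75]))  # smaller blob dropped

  expect_warning(empty <- make_factin_mask(matrix(1, 5, 5)), "variance")
  expect_false(any(empty))
})

test_that("mask area tracks the generated veil plus filopodia raster", {
  gp <- growth_cone_params(state = "spread", noise_sd = 0, seed = 3)
  gc <- simulate_growth_cone(gp, psf_sigma_px = 0)
  mask <- make_factin_mask(gc$image, scale = gc$scale,
                           threshold_method = "fixed", fixed_value = 0.5)
  truth_area <- sum(gc$image > 0.5)
  expect_lt(abs(sum(mask) - truth_area) / truth_area, 0.1)
})

test_that("ROI intensity subtracts background and respects equivariance", {
  img <- matrix(20, 60, 60)
  roi <- disc_mask(60, 1, c(30, 30), 10)
  img[roi] <- 100
  m <- measure_roi_intensity(img, roi, scale = 1)
  expect_equal(m$mean_intensity, 80)
  expect_equal(m$mask_area, sum(roi))

  flat <- measure_roi_intensity(matrix(50, 60, 60), roi, scale = 1)
  expect_equal(flat$mean_intensity, 0)

  # adding a constant leaves the annulus-subtracted mean unchanged;
  # scaling scales it
  m2 <- measure_roi_intensity(img + 17, roi, scale = 1)
  expect_equal(m2$mean_intensity, m$mean_intensity)
  m3 <- measure_roi_intensity(img * 3, roi, scale = 1)
  expect_equal(m3$mean_intensity, 3 * m$mean_intensity)

  expect_error(measure_roi_intensity(img, roi & FALSE), "empty")
})

test_that("group intensity ratios are recovered from noisy synthetic fields", {
  set.seed(42)
  one_field <- function(level) {
    img <- matrix(rnorm(60 * 60, 10, level * 0.1), 60, 60)
    roi <- disc_mask(60, 1, c(30, 30), 10)
    img[roi] <- img[roi] + level
    measure_roi_intensity(img, roi, scale = 1)$mean_intensity
  }
  a <- replicate(30, one_field(100))
  b <- replicate(30, one_field(50))
  ratio <- mean(b) / mean(a)
  se <- ratio * sqrt(var(a) / (30 * mean(a)^2) + var(b) / (30 * mean(b)^2))
  expect_lt(abs(ratio - 0.5), 3 * se + 0.02)
})

test_that("normalization to control has mean one, preserves order, idempotent", {
  df <- data.frame(value = c(2, 4, 6),
                   condition = c("control", "control", "treated"))
  out <- normalize_to_control(df, "control")
  expect_equal(out$normalized_value, c(2 / 3, 4 / 3, 2))
  expect_equal(mean(out$normalized_value[out$condition == "control"]), 1)

  single <- normalize_to_control(
    data.frame(value = 7, condition = "control"), "control")
  expect_equal(single$normalized_value, 1)

  again <- normalize_to_control(
    data.frame(value = out$normalized_value, condition = out$condition),
    "control")
  expect_equal(again$normalized_value, out$normalized_value)
  expect_error(normalize_to_control(df, "missing"), "empty")
})

test_that("veil and filopodia are recovered from constructed masks", {
  sc <- 0.25; n <- 256
  disc <- disc_mask(n, sc, c(32, 32), 8)
  mask <- disc
  for (a in c(0, 2 * pi / 3, 4 * pi / 3)) {
    df <- data.frame(trace_id = 1, vertex_index = 1:2,
                     x_um = 32 + c(8, 20) * cos(a),
                     y_um = 32 + c(8, 20) * sin(a))
    mask <- mask | rasterize_traces(df, c(n, n), sc)
  }
  seg <- extract_filopodia(mask, scale = sc)
  expect_equal(seg$veil_area, pi * 64, tolerance = 0.05)
  expect_equal(nrow(seg$filopodia), 3)
  expect_equal(seg$filopodia$length_um, rep(12, 3), tolerance = 0.05)

  bare <- extract_filopodia(disc, scale = sc)
  expect_equal(nrow(bare$filopodia), 0)
  expect_gt(bare$veil_area, 0)

  line <- rasterize_traces(
    data.frame(trace_id = 1, vertex_index = 1:2,
               x_um = c(22, 42), y_um = c(32, 32)), c(n, n), sc)
  seg_l <- extract_filopodia(line, scale = sc)
  expect_lt(seg_l$veil_area, 1)
  expect_equal(nrow(seg_l$filopodia), 1)
  expect_equal(seg_l$filopodia$length_um, 20, tolerance = 0.05)
})

test_that("collapse rule applies the veil/count/length conjunction", {
  expect_true(classify_collapse(fake_seg(0, 5))$collapsed)
  expect_false(classify_collapse(fake_seg(0, c(12, 12)))$collapsed)
  expect_false(classify_collapse(fake_seg(40, rep(8, 8)))$collapsed)
  expect_true(classify_collapse(fake_seg(5, numeric(0)))$collapsed)
  expect_false(classify_collapse(fake_seg(5.1, numeric(0)))$collapsed)
  # exactly 2 long filopodia with no veil: not collapsed by default
  expect_false(classify_collapse(fake_seg(0, c(10, 10)))$collapsed)
})

test_that("collapse table tallies conditions and percentages", {
  calls <- data.frame(
    condition = rep(c("control", "treated"), c(10, 8)),
    collapsed = c(rep(c(TRUE, FALSE), c(4, 6)), rep(c(TRUE, FALSE), c(6, 2))))
  tab <- collapse_table(calls)
  expect_equal(tab$percent_collapsed[tab$condition == "control"], 40)
  expect_equal(attr(tab, "counts")["collapsed", "treated"], 6L)

  withlev <- calls
  withlev$condition <- factor(withlev$condition,
                              levels = c("control", "treated", "ghost"))
  expect_warning(collapse_table(withlev), "ghost")
})
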