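test_that("mean filter obeys its neighbourhood definition", {
  g <- grayscale_volume(array(7L, c(5, 5, 5)), 1)
  expect_identical(as.vector(mean_filter_smooth(g, 0)), as.vector(g))
  # constant image unchanged by any radius
  expect_true(all(mean_filter_smooth(g, 2) == 7))
  # single bright centre voxel in 3^3, radius 1: centre = v/27 + 26 bg/27
  a <- array(10, c(3, 3, 3)); a[2, 2, 2] <- 100
  sm <- mean_filter_smooth(grayscale_volume(a, 1), 1)
  expect_equal(sm[2, 2, 2], 100 / 27 + 26 * 10 / 27, tolerance = 1e-12)
  # corner voxel uses a clipped 2x2x2 neighbourhood
  expect_equal(sm[1, 1, 1], (100 + 7 * 10) / 8, tolerance = 1e-12)
})

test_that("thresholding follows the strictly-greater convention", {
  a <- array(c(10L, 20L, 30L, 40L), c(2, 2, 1))
  g <- grayscale_volume(array(rep(a, 4), c(2, 2, 4)), 1)
  expect_true(all(segment_by_threshold(g, 5)))          # all solid
  expect_false(any(segment_by_threshold(g, 40)))        # all pore (> strictly)
  seg <- segment_by_threshold(g, 20)
  expect_identical(sum(seg), sum(g > 20))
  expect_identical(attr(seg, "threshold_used"), 20)
})

test_that("histogram-minimum threshold finds the valley", {
  # two delta peaks at 50 and 200: empty valley, lowest bin convention -> 51
  v <- c(rep(50L, 600), rep(200L, 500))
  g <- grayscale_volume(array(v, c(11, 10, 10)), 1)
  expect_identical(histogram_minimum_threshold(g), 51L)
  # bimodal Gaussian mixture: valley between the modes, across realizations
  for (sd in 1:5) {
    set.seed(sd)
    x <- as.integer(round(c(rnorm(4000, 60, 20), rnorm(4000, 180, 20))))
    g2 <- grayscale_volume(array(x, c(20, 20, 20)), 1)
    tv <- histogram_minimum_threshold(g2)
    expect_gte(tv, 100); expect_lte(tv, 140)
  }
  # constant image: no two modes
  expect_error(histogram_minimum_threshold(grayscale_volume(array(5L, c(4, 4, 4)), 1)),
               "unimodal|manual")
})

test_that("threshold calibration recovers a known area rate", {
  set.seed(11)
  solid <- array(stats::runif(32^3) < 0.5186, c(32, 32, 32))
  b <- binary_microstructure(solid, 1)
  g <- render_grayscale(b, noise_spec(blur_sigma = 0, noise_sd = 8,
                                      fg_level = 200, bg_level = 50, seed = 5))
  cal <- calibrate_threshold_to_area_rate(g, target_rate = mean(solid))
  achieved <- cal$area_rate_by_tv$area_rate[match(cal$chosen_tv, cal$area_rate_by_tv$tv)]
  expect_lt(abs(achieved - mean(solid)), 0.01)
  # area rate is monotone non-increasing in the threshold
  expect_true(all(diff(cal$area_rate_by_tv$area_rate) <= 1e-12))
  # chosen threshold attains the minimal deviation (exhaustive check)
  dev <- abs(cal$area_rate_by_tv$area_rate - cal$target_rate)
  expect_equal(min(dev), dev[match(cal$chosen_tv, cal$area_rate_by_tv$tv)])
  # target 0 selects the emptiest segmentation (largest threshold scanned)
  cal0 <- calibrate_threshold_to_area_rate(g, target_rate = 0)
  expect_identical(cal0$chosen_tv, max(cal0$area_rate_by_tv$tv))
})

test_that("cubic ROI cropping preserves content and validates bounds", {
  set.seed(4)
  a <- array(sample(0:255, 20^3, TRUE), c(20, 20, 20))
  g <- grayscale_volume(a, 3)
  expect_identical(as.vector(crop_cubic_roi(g, c(1, 1, 1), 20)), as.vector(g))
  sub <- crop_cubic_roi(g, c(3, 4, 5), 8)
  expect_identical(dim(sub), c(8L, 8L, 8L))
  expect_identical(voxel_size(sub), 3)
  expect_identical(sub[1, 1, 1], a[3, 4, 5])
  expect_error(crop_cubic_roi(g, c(15, 1, 1), 8), "axis x")
  # porosity of a crop equals porosity of that region in the full volume
  b <- binary_microstructure(a > 127, 1)
  cb <- crop_cubic_roi(b, c(3, 4, 5), 8)
  expect_identical(compute_porosity(cb), mean(a[3:10, 4:11, 5:12] <= 127))
})

test_that("RVE convergence assessment behaves on homogeneous and structured media", {
  set.seed(9)
  hom <- binary_microstructure(array(stats::runif(48^3) < 0.5, c(48, 48, 48)), 1)
  rep_h <- assess_rve_convergence(hom, edge_sizes = c(8, 16, 32, 48),
                                  n_positions = 8, seed = 1)
  expect_lte(rep_h$recommended_edge, 32)
  # a single coarse channel needs a larger RVE than the homogeneous medium
  ch <- generate_channel_phantom(c(64, 64, 64), 1, radius_um = 16, axis = "z")
  rep_c <- assess_rve_convergence(ch, edge_sizes = c(8, 16, 32, 64),
                                  n_positions = 8, seed = 1)
  rec_c <- if (is.na(rep_c$recommended_edge)) 65L else rep_c$recommended_edge
  expect_gt(rec_c, rep_h$recommended_edge)
  # the full volume alone is trivially converged (single position, SD 0)
  rep_f <- assess_rve_convergence(hom, edge_sizes = 48, n_positions = 1, seed = 1)
  expect_identical(rep_f$recommended_edge, 48L)
})
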