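test_that("channel phantom matches its analytic porosity and geometry", {
  ch <- generate_channel_phantom(c(64, 64, 64), 1, radius_um = 16, axis = "z")
  expect_rel(compute_porosity(ch), pi * 16^2 / 64^2, 0.03)
  # deterministic: two calls identical
  ch2 <- generate_channel_phantom(c(64, 64, 64), 1, radius_um = 16, axis = "z")
  expect_identical(as.vector(ch), as.vector(ch2))
  # channel along x percolates along x and is straight
  chx <- generate_channel_phantom(c(40, 32, 32), 1, radius_um = 0.4 * 32, axis = "x")
  tx <- compute_tortuosity(chx, "pore", "x")
  expect_true(tx$percolating)
  expect_rel(tx$tau, 1, 1e-6)
  expect_error(generate_channel_phantom(c(32, 32, 32), 1, radius_um = 20, axis = "z"),
               "diameter")
})

test_that("plate phantom porosity is exact and degenerate cases behave", {
  pl <- generate_plate_phantom(c(64, 64, 64), 1, gap_um = 16, normal_axis = "z")
  expect_identical(compute_porosity(pl), 16 / 64)
  full <- generate_plate_phantom(c(16, 16, 16), 1, gap_um = 16, normal_axis = "z")
  expect_identical(compute_porosity(full), 1)
  expect_error(generate_plate_phantom(c(16, 16, 16), 2, gap_um = 1, normal_axis = "z"),
               "at least one voxel")
})

test_that("fiber phantom hits its porosity target, percolates and is reproducible", {
  spec <- phantom_spec(shape = c(64, 64, 64), seed = 1)
  ph <- generate_fiber_phantom(spec)
  expect_true(abs(compute_porosity(ph) - spec$target_porosity) <= 0.02)
  expect_true(attr(ph, "porosity_converged"))
  expect_true(phase_percolates(ph, "pore", spec$alignment_axis))
  ph2 <- generate_fiber_phantom(spec)
  expect_identical(as.vector(ph), as.vector(ph2))
  ph3 <- generate_fiber_phantom(phantom_spec(shape = c(64, 64, 64), seed = 2))
  expect_false(identical(as.vector(ph), as.vector(ph3)))
})

test_that("straight (unmodulated, unwavy) tubes have tortuosity ~ 1", {
  spec <- phantom_spec(shape = c(48, 48, 48), waviness = 0,
                       modulation_amplitude = 0, seed = 3)
  ph <- generate_fiber_phantom(spec)
  tz <- compute_tortuosity(ph, "pore", "z")
  expect_true(tz$percolating)
  expect_lt(abs(tz$tau - 1), 0.02)
})

test_that("grayscale rendering supports exact and noisy recovery", {
  b <- generate_plate_phantom(c(24, 24, 24), 1, gap_um = 8, normal_axis = "z")
  clean <- render_grayscale(b, noise_spec(blur_sigma = 0, noise_sd = 0,
                                          fg_level = 200, bg_level = 50))
  expect_setequal(unique(as.vector(clean)), c(50L, 200L))
  rec <- segment_by_threshold(clean, 125)
  expect_identical(as.vector(rec), as.vector(solid_mask(b)))
  # midpoint threshold on a noisy rendering misclassifies < 1% of voxels
  noisy <- render_grayscale(b, noise_spec(blur_sigma = 0, noise_sd = 10,
                                          fg_level = 200, bg_level = 50, seed = 7))
  seg <- segment_by_threshold(noisy, 125)
  expect_lt(mean(as.vector(seg) != as.vector(solid_mask(b))), 0.01)
  # swapped levels invert the segmentation
  swapped <- render_grayscale(b, noise_spec(blur_sigma = 0, noise_sd = 0,
                                            fg_level = 50, bg_level = 200))
  seg_sw <- segment_by_threshold(swapped, 125)
  expect_identical(as.vector(seg_sw), as.vector(!solid_mask(b)))
  # determinism under the noise seed
  noisy2 <- render_grayscale(b, noise_spec(blur_sigma = 0, noise_sd = 10,
                                           fg_level = 200, bg_level = 50, seed = 7))
  expect_identical(as.vector(noisy), as.vector(noisy2))
})

test_that("stress-strain generator reproduces closed forms", {
  # yeoh3 with C10 = 1, others 0: sigma(lambda = 2) = 2 (2 - 1/4) = 3.5
  cv <- generate_stress_strain(curve_spec(model_name = "yeoh3",
                                          params = list(C10 = 1, C20 = 0, C30 = 0),
                                          max_strain = 1, n_points = 101))
  expect_equal(cv$stress_MPa[cv$stretch == 2], 3.5, tolerance = 1e-12)
  expect_identical(cv$stress_MPa[1], 0)
  # piecewise J mode: exact post-toe slope before noise
  cj <- generate_stress_strain(curve_spec(linear_modulus_MPa = 38.5,
                                          toe_strain = 0.13, max_strain = 0.4,
                                          n_points = 100))
  post <- cj[cj$strain > 0.14, ]
  slopes <- diff(post$stress_MPa) / diff(post$strain)
  expect_true(all(abs(slopes - 38.5) < 1e-9))
  # noise clipping flag
  tiny <- generate_stress_strain(curve_spec(model_name = "neo_hookean",
                                            params = list(C10 = 1e-4),
                                            max_strain = 0.2, n_points = 50,
                                            noise_rel_sd = 5, seed = 2))
  expect_gte(attr(tiny, "clipped_points"), 1)
  expect_true(all(tiny$stress_MPa >= 0))
})

test_that("falling-head generator round-trips and scales linearly", {
  fh <- generate_falling_head_record(3.17e-12, a_m2 = 2.16e-4, A_m2 = 2.74e-6,
                                     H_m = 1e-2, L1_m = 1.46, L2_m = 1.44)
  k <- conductivity_to_permeability(falling_head_conductivity(fh))$k_m2
  expect_rel(k, 3.17e-12, 1e-3)
  # L1 = L2: no head drop, zero elapsed time
  z <- generate_falling_head_record(1e-12, 1e-4, 1e-6, 1e-2, 0.45, 0.45)
  expect_identical(z$t_s, 0)
  # doubling the standpipe area doubles the elapsed time
  t1 <- generate_falling_head_record(1e-12, 1e-4, 1e-6, 1e-2, 0.45, 0.40)$t_s
  t2 <- generate_falling_head_record(1e-12, 2e-4, 1e-6, 1e-2, 0.45, 0.40)$t_s
  expect_equal(t2, 2 * t1, tolerance = 1e-12)
  expect_error(generate_falling_head_record(-1e-12, 1e-4, 1e-6, 1e-2, 0.45, 0.4),
               "positive")
})
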