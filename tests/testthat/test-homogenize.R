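test_that("a homogeneous cube recovers the solid modulus on every axis", {
  b <- binary_microstructure(array(TRUE, c(12, 12, 12)), 1)
  r <- homogenize_effective_moduli(b, 10, 0.49)
  for (ax in c("x", "y", "z")) expect_rel(r$E_MPa[[ax]], 10, 0.01)
})

test_that("a laminate follows the rule of mixtures and is void in series", {
  lam <- binary_microstructure(laminate_mask(16, 2), 1)   # fraction 0.5, normal z
  r <- homogenize_effective_moduli(lam, 10, 0.49)
  expect_rel(r$E_MPa[["x"]], 5, 0.03)   # Voigt bound exact for this geometry
  expect_rel(r$E_MPa[["y"]], 5, 0.03)
  expect_identical(r$E_MPa[["z"]], 0)   # plates in series with void
})

test_that("effective moduli respect Voigt bounds and scale linearly", {
  set.seed(21)
  m <- array(stats::runif(16^3) < 0.7, c(16, 16, 16))
  b <- binary_microstructure(m, 1)
  r1 <- homogenize_effective_moduli(b, 10, 0.3, axes = "z")
  voigt <- mean(m) * 10
  expect_gte(r1$E_MPa[["z"]], 0)
  expect_lte(r1$E_MPa[["z"]], voigt * (1 + 1e-9))
  # linearity in the solid modulus (exact to solver tolerance)
  r2 <- homogenize_effective_moduli(b, 20, 0.3, axes = "z")
  expect_rel(r2$E_MPa[["z"]] / r1$E_MPa[["z"]], 2, 1e-9)
})

test_that("axis permutation of the geometry permutes the moduli", {
  set.seed(8)
  m <- array(stats::runif(12^3) < 0.75, c(12, 12, 12))
  b <- binary_microstructure(m, 1)
  r <- homogenize_effective_moduli(b, 10, 0.35)
  # swap x and z in the geometry
  b_perm <- binary_microstructure(aperm(m, c(3, 2, 1)), 1)
  rp <- homogenize_effective_moduli(b_perm, 10, 0.35)
  expect_equal(rp$E_MPa[["x"]], r$E_MPa[["z"]], tolerance = 1e-8)
  expect_equal(rp$E_MPa[["z"]], r$E_MPa[["x"]], tolerance = 1e-8)
  expect_equal(rp$E_MPa[["y"]], r$E_MPa[["y"]], tolerance = 1e-8)
})

test_that("solid-modulus calibration exploits linearity and confirms", {
  b <- binary_microstructure(array(TRUE, c(10, 10, 10)), 1)
  sm <- calibrate_solid_modulus(b, 10, axis = "z")
  expect_rel(as.numeric(sm), 10, 0.01)
  expect_rel(attr(sm, "confirmed_E_MPa"), 10, 0.01)
  # doubling the target doubles the returned modulus exactly
  ph <- generate_fiber_phantom(phantom_spec(shape = c(20, 20, 20),
                                            tube_radius_mean_um = 3,
                                            seed = 2))
  s1 <- as.numeric(calibrate_solid_modulus(ph, 38.5, axis = "z"))
  s2 <- as.numeric(calibrate_solid_modulus(ph, 77, axis = "z"))
  expect_rel(s2 / s1, 2, 1e-9)
  # non-percolating solid errors
  void <- binary_microstructure(laminate_mask(12, 2), 1)
  expect_error(calibrate_solid_modulus(void, 10, axis = "z"), "percolate")
})
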