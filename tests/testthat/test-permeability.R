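test_that("darcy permeability identities and flags", {
  out <- darcy_permeability(L_m = 1, A_m2 = 1, Q_m3_s = 1, dP_Pa = 1,
                            fluid = fluid_properties(viscosity = 1))
  expect_identical(out$k_m2, 1)
  expect_error(darcy_permeability(L_m = 1, A_m2 = 1, Q_m3_s = 1, dP_Pa = 0),
               "positive")
})

test_that("the Stokes solver reproduces duct closed forms at modest resolution", {
  # slit between solid walls, slip lateral planes: plane Poiseuille
  pl <- generate_plate_phantom(c(32, 24, 32), 1, gap_um = 8, normal_axis = "z")
  sol <- solve_stokes_flow(pl, axis = "x", Q_m3_s = 1e-13, lateral = "slip")
  k <- darcy_permeability(sol)$k_m2
  expect_rel(k, (8e-6)^3 / (12 * 32e-6), 0.05)
  expect_lt(sol$residuals["divergence"], 1e-8)
  expect_lt(sol$residuals["momentum"], 1e-6)
  # with no-slip lateral walls the duct is stiffer (Cornish correction)
  sol_w <- solve_stokes_flow(pl, axis = "x", Q_m3_s = 1e-13, lateral = "noslip")
  expect_lt(darcy_permeability(sol_w)$k_m2, k)
})

test_that("permeability is independent of the imposed flow rate", {
  pl <- generate_plate_phantom(c(24, 16, 24), 1, gap_um = 8, normal_axis = "z")
  k1 <- darcy_permeability(solve_stokes_flow(pl, "x", Q_m3_s = 1e-13))$k_m2
  k2 <- darcy_permeability(solve_stokes_flow(pl, "x", Q_m3_s = 2e-13))$k_m2
  expect_rel(k2 / k1, 1, 0.01)
  # and dP doubles with Q (Stokes linearity)
  s1 <- solve_stokes_flow(pl, "x", Q_m3_s = 1e-13)
  s2 <- solve_stokes_flow(pl, "x", Q_m3_s = 2e-13)
  expect_rel(s2$dP_Pa / s1$dP_Pa, 2, 0.01)
})

test_that("permeability scales with the square of the voxel size", {
  m <- generate_channel_phantom(c(24, 24, 24), 1, radius_um = 6, axis = "z")
  m2 <- binary_microstructure(array(solid_mask(m), dim(m)), 2)  # same voxels, 2 um
  k1 <- darcy_permeability(solve_stokes_flow(m, "z", Q_m3_s = 1e-14))$k_m2
  k2 <- darcy_permeability(solve_stokes_flow(m2, "z", Q_m3_s = 1e-14))$k_m2
  expect_rel(k2 / k1, 4, 1e-6)
})

test_that("dilating the pore phase never decreases permeability", {
  a <- generate_channel_phantom(c(24, 24, 24), 1, radius_um = 5, axis = "z")
  b <- generate_channel_phantom(c(24, 24, 24), 1, radius_um = 7, axis = "z")
  ka <- darcy_permeability(solve_stokes_flow(a, "z", Q_m3_s = 1e-14))$k_m2
  kb <- darcy_permeability(solve_stokes_flow(b, "z", Q_m3_s = 1e-14))$k_m2
  expect_gt(kb, ka)
})

test_that("non-percolating pore space is rejected", {
  blocked <- array(TRUE, c(12, 12, 12))
  blocked[4:8, 4:8, 1:5] <- FALSE    # dead-end pocket
  expect_error(solve_stokes_flow(binary_microstructure(blocked, 1), "z"),
               "percolate")
})

test_that("Reynolds number follows its definition and gates Darcy validity", {
  pl <- generate_plate_phantom(c(16, 12, 16), 1, gap_um = 8, normal_axis = "z")
  sol <- solve_stokes_flow(pl, "x", Q_m3_s = 1e-13)
  d <- 11.8e-6
  Re <- reynolds_number(sol, d)
  v <- sol$Q_m3_s / (sol$porosity * sol$A_m2)
  expect_equal(Re, 1000 * v * d / 1e-3, tolerance = 1e-12)
  # linear in Q
  sol2 <- solve_stokes_flow(pl, "x", Q_m3_s = 1e-7)
  expect_rel(reynolds_number(sol2, d) / Re, 1e-7 / 1e-13, 1e-9)
  # validity flag
  res <- darcy_permeability(sol, characteristic_length_m = d)
  expect_true(res$valid_darcy)
})

test_that("aggregation uses the population standard deviation", {
  agg <- aggregate_permeability(c(3.29e-12, 2.84e-12, 3.18e-12))
  expect_rel(agg$mean, 3.10e-12, 0.01)
  expect_rel(agg$sd_pop, 1.91e-13, 0.01)
  same <- aggregate_permeability(rep(2e-12, 4))
  expect_identical(same$sd_pop, 0)
})
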