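test_that("uniaxial closed forms satisfy their identities", {
  p <- hyperelastic_params("yeoh3", list(C10 = 1, C20 = 0, C30 = 0))
  expect_equal(uniaxial_stress(p, 2), 3.5, tolerance = 1e-12)
  for (m in list(
    hyperelastic_params("yeoh3", list(C10 = 2, C20 = -0.1, C30 = 0.05)),
    hyperelastic_params("mooney_rivlin", list(C10 = 1, C01 = 0.5)),
    hyperelastic_params("ogden1", list(mu1 = 1.2, alpha1 = 3)),
    hyperelastic_params("neo_hookean", list(C10 = 2))
  )) {
    expect_equal(uniaxial_stress(m, 1), 0, tolerance = 1e-12)
  }
  # small-strain slope of yeoh3 equals 6 C10 (finite-difference oracle)
  py <- hyperelastic_params("yeoh3", list(C10 = 2, C20 = -0.1, C30 = 0.05))
  dl <- 1e-6
  slope <- (uniaxial_stress(py, 1 + dl) - uniaxial_stress(py, 1 - dl)) / (2 * dl)
  expect_rel(slope, 6 * 2, 1e-3)
  expect_error(hyperelastic_params("mystery", list(a = 1)), "unknown")
})

test_that("load scaling preserves nominal stress", {
  expect_equal(scale_load_to_rve(10, 100e-6, 1e-6), 0.1, tolerance = 1e-12)
  expect_identical(scale_load_to_rve(7, 2e-6, 2e-6), 7)
  F_rve <- scale_load_to_rve(12, 5e-6, 1.3e-6)
  expect_equal(F_rve / 1.3e-6, 12 / 5e-6, tolerance = 1e-12)
})

test_that("hyperelastic fitting recovers generating coefficients", {
  cv <- generate_stress_strain(curve_spec(
    model_name = "yeoh3", params = list(C10 = 2, C20 = -0.1, C30 = 0.05),
    max_strain = 0.3, n_points = 50
  ))
  f <- fit_hyperelastic(cv, "yeoh3")
  expect_rel(f$params$coefficients$C10, 2, 1e-6)
  expect_rel(f$params$coefficients$C20, -0.1, 1e-6)
  expect_rel(f$params$coefficients$C30, 0.05, 1e-6)
  expect_lt(f$fit_mse, 1e-20)
  # linear data at tiny strains: 6 C10 ~ E
  lin <- tibble::tibble(strain = seq(0, 0.01, length.out = 40),
                        stress_MPa = 30 * seq(0, 0.01, length.out = 40))
  fl <- fit_hyperelastic(lin, "yeoh3")
  expect_rel(6 * fl$params$coefficients$C10, 30, 0.02)
  # parameter recovery under noise: median C10 error over 20 seeds <= 5%
  errs <- vapply(1:20, function(sd) {
    cvn <- generate_stress_strain(curve_spec(
      model_name = "yeoh3", params = list(C10 = 2, C20 = -0.1, C30 = 0.05),
      max_strain = 0.3, n_points = 50, noise_rel_sd = 0.01, seed = sd
    ))
    abs(fit_hyperelastic(cvn, "yeoh3")$params$coefficients$C10 / 2 - 1)
  }, numeric(1))
  expect_lte(stats::median(errs), 0.05)
  # ogden fit is exact on ogden data
  cvo <- generate_stress_strain(curve_spec(
    model_name = "ogden1", params = list(mu1 = 1.5, alpha1 = 4),
    max_strain = 0.5, n_points = 60
  ))
  fo <- fit_hyperelastic(cvo, "ogden1")
  expect_rel(fo$params$coefficients$mu1, 1.5, 1e-4)
  expect_rel(fo$params$coefficients$alpha1, 4, 1e-4)
})

test_that("nested models never fit worse and selection favours parsimony", {
  cv <- generate_stress_strain(curve_spec(
    model_name = "neo_hookean", params = list(C10 = 2),
    max_strain = 0.4, n_points = 100, noise_rel_sd = 0.01, seed = 4
  ))
  f_neo <- fit_hyperelastic(cv, "neo_hookean")
  f_mr <- fit_hyperelastic(cv, "mooney_rivlin")
  f_y <- fit_hyperelastic(cv, "yeoh3")
  expect_lte(f_mr$fit_mse, f_neo$fit_mse * (1 + 1e-9))
  expect_lte(f_y$fit_mse, f_neo$fit_mse * (1 + 1e-9))
  ms <- select_best_model(cv)
  expect_identical(ms$best$model_name, "neo_hookean")
  # strongly curved yeoh data: the generating model wins outright
  cvy <- generate_stress_strain(curve_spec(
    model_name = "yeoh3", params = list(C10 = 0.5, C20 = 0.3, C30 = 0.2),
    max_strain = 0.6, n_points = 100, noise_rel_sd = 0.01, seed = 3
  ))
  msy <- select_best_model(cvy)
  expect_identical(msy$best$model_name, "yeoh3")
  # single candidate returned trivially
  ms1 <- select_best_model(cvy, candidates = "mooney_rivlin")
  expect_identical(ms1$best$model_name, "mooney_rivlin")
  # tidy/glance surface
  g <- glance(msy$best)
  expect_identical(g$model, "yeoh3")
  expect_equal(g$E0_MPa, 6 * msy$best$params$coefficients$C10, tolerance = 1e-12)
})

test_that("linear-region detection finds the toe and the modulus", {
  cv <- generate_stress_strain(curve_spec(
    linear_modulus_MPa = 38.5, toe_strain = 0.13, max_strain = 0.4, n_points = 120
  ))
  lr <- linear_region_modulus(cv)
  expect_rel(lr$modulus_MPa, 38.5, 0.01)
  expect_lt(abs(lr$toe_strain - 0.13), 0.02)
  expect_true(lr$converged)
  # pure linear curve: toe 0, exact slope
  linc <- tibble::tibble(strain = seq(0, 0.3, length.out = 50),
                         stress_MPa = 20 * seq(0, 0.3, length.out = 50))
  lr2 <- linear_region_modulus(linc)
  expect_equal(lr2$modulus_MPa, 20, tolerance = 1e-9)
  expect_identical(lr2$toe_strain, 0)
  # 1% noise: slope within 3%
  cv3 <- generate_stress_strain(curve_spec(
    linear_modulus_MPa = 38.5, toe_strain = 0.13, max_strain = 0.4,
    n_points = 120, noise_rel_sd = 0.01, seed = 5
  ))
  lr3 <- linear_region_modulus(cv3)
  expect_rel(lr3$modulus_MPa, 38.5, 0.03)
})

test_that("unstable fits are flagged and ranked after stable ones", {
  # strongly softening yeoh parameters give a negative tangent in range
  lam <- seq(1, 1.6, length.out = 40)
  p_bad <- hyperelastic_params("yeoh3", list(C10 = 1, C20 = -1.2, C30 = 0))
  cvb <- tibble::tibble(stretch = lam, stress_MPa = uniaxial_stress(p_bad, lam))
  fb <- fit_hyperelastic(cvb, "yeoh3")
  expect_false(fb$stable)
})
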