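test_that("porosity matches counting oracles and phases sum to one", {
  slab <- generate_plate_phantom(c(32, 32, 32), 1, gap_um = 16, normal_axis = "z")
  expect_identical(compute_porosity(slab), 0.5)
  sph <- binary_microstructure(sphere_mask(64, 16), 1)
  expect_rel(compute_porosity(sph), 1 - (4 / 3) * pi * 16^3 / 64^3, 0.01)
  # solid fraction + pore fraction = 1 exactly
  expect_identical(compute_porosity(sph) + mean(solid_mask(sph)), 1)
})

test_that("SAVR estimators agree with face-counting and closed-form oracles", {
  cube <- array(FALSE, c(64, 64, 64)); cube[17:48, 17:48, 17:48] <- TRUE
  b <- binary_microstructure(cube, 1)
  fc_ref <- 6 * 32^2 / 64^3
  expect_equal(compute_savr(b, "face_count"), fc_ref, tolerance = 1e-12)
  expect_rel(compute_savr(b, "isosurface"), fc_ref, 0.1)
  # sphere r = 10 um: isosurface area within 5% of 4 pi r^2
  sph <- binary_microstructure(sphere_mask(40, 10), 1)
  expect_rel(compute_savr(sph, "isosurface"), 4 * pi * 100 / 40^3, 0.05)
  # face counting overestimates smooth surfaces by a bounded factor
  ratio <- compute_savr(sph, "face_count") / compute_savr(sph, "isosurface")
  expect_gt(ratio, 1); expect_lt(ratio, 1.6)
  # all-solid volume: no internal interface, boundary excluded
  full <- binary_microstructure(array(TRUE, c(16, 16, 16)), 1)
  expect_warning(expect_identical(compute_savr(full, "face_count"), 0), NA)
  expect_identical(compute_savr(full, "isosurface"), 0)
})

test_that("geodesic tortuosity matches straight and L-shaped oracles", {
  ch <- generate_channel_phantom(c(32, 32, 64), 1, radius_um = 8, axis = "z")
  tz <- compute_tortuosity(ch, "pore", "z")
  expect_lt(abs(tz$tau - 1), 0.02)
  # all-pore volume: tau exactly 1 for every start voxel
  ap <- binary_microstructure(array(FALSE, c(10, 10, 16)), 1)
  ta <- compute_tortuosity(ap, "pore", "z")
  expect_lt(abs(ta$tau - 1), 1e-6)
  expect_identical(ta$n_paths, 100L)
  # L-channel: 50 straight + 50 diagonal steps over extent 100
  lc <- l_channel()
  tl <- compute_tortuosity(lc, "pore", "z", connectivity = 26)
  expect_equal(tl$tau, (50 + 50 * sqrt(2)) / 100, tolerance = 1e-6)
  # 6-connected metric forbids diagonals: a rectangular detour costs the
  # full 50 + 50 + 50 steps over extent 100
  tl6 <- compute_tortuosity(l_channel_rect(), "pore", "z", connectivity = 6)
  expect_equal(tl6$tau, 1.5, tolerance = 1e-6)
  # non-percolating phase is reported, not inverted
  blocked <- array(TRUE, c(8, 8, 8)); blocked[4, 4, 1:3] <- FALSE
  tb <- compute_tortuosity(binary_microstructure(blocked, 1), "pore", "z")
  expect_false(tb$percolating)
  expect_true(is.na(tb$tau))
})

test_that("tortuosity weakly decreases when obstacles are removed", {
  base <- array(FALSE, c(24, 24, 48))      # all pore
  obst <- base
  obst[1:20, , seq(8, 40, by = 8)] <- TRUE  # baffles forcing detours
  b_obst <- binary_microstructure(obst, 1)
  b_open <- binary_microstructure(base, 1)
  t_obst <- compute_tortuosity(b_obst, "pore", "z")$tau
  t_open <- compute_tortuosity(b_open, "pore", "z")$tau
  expect_gte(t_obst, t_open - 1e-12)
  expect_gt(t_obst, 1.05)
})

test_that("object separation and ESD recover known objects", {
  # two disjoint spheres -> two labels
  m <- sphere_mask(48, 8, c(13, 24, 24)) | sphere_mask(48, 8, c(36, 24, 24))
  b <- binary_microstructure(!m, 1)        # spheres as pore
  lab <- separate_objects(b, "pore")
  expect_identical(max(lab), 2L)
  # label conservation: every phase voxel labelled exactly once
  expect_identical(sum(lab > 0), sum(m))
  # overlapping spheres split near the neck, centroids near the centres
  mo <- sphere_mask(40, 9, c(12, 12, 12)) | sphere_mask(40, 9, c(28, 12, 12))
  bo <- binary_microstructure(!mo, 1)
  lo <- separate_objects(bo, "pore")
  expect_identical(max(lo), 2L)
  cents <- sapply(1:2, function(L) {
    w <- which(lo == L, arr.ind = TRUE); mean(w[, 1])
  })
  expect_lt(abs(min(cents) - 12), 2)
  expect_lt(abs(max(cents) - 28), 2)
  # single sphere: one label, ESD = 2 r within 5%
  ms <- sphere_mask(40, 10)
  bs <- binary_microstructure(!ms, 1)
  ls <- separate_objects(bs, "pore")
  expect_identical(max(ls), 1L)
  e <- esd_distribution(ls)
  expect_rel(e$mean_um, 20, 0.05)
  # cube edge 10 um: ESD = (6000/pi)^(1/3)
  mc <- array(FALSE, c(20, 20, 20)); mc[6:15, 6:15, 6:15] <- TRUE
  ec <- esd_distribution(separate_objects(binary_microstructure(!mc, 1), "pore"))
  expect_rel(ec$mean_um, (6 * 1000 / pi)^(1 / 3), 0.01)
})

test_that("the endoneurium phantom's measured pore size brackets its design target", {
  ph <- generate_fiber_phantom(phantom_spec(seed = 1))
  e <- esd_distribution(separate_objects(ph, "pore"))
  expect_gte(e$mean_um, 9.0)
  expect_lte(e$mean_um, 14.6)
})

test_that("morphometry wrapper assembles a coherent result", {
  ph <- generate_fiber_phantom(phantom_spec(shape = c(48, 48, 48), seed = 5))
  res <- morphometry(ph, phases = "pore", axes = "z")
  expect_s3_class(res, "morphometry_result")
  expect_identical(res$porosity, compute_porosity(ph))
  expect_gt(res$savr_um_inv, 0)
  expect_gt(res$savr_face_count_um_inv, res$savr_um_inv)
  expect_true(all(res$tortuosity$tau[res$tortuosity$percolating] >= 1 - 1e-9))
  # label conservation through the wrapper
  expect_identical(sum(res$pore_size$table$n_voxels), sum(pore_mask(ph)))
  td <- tidy(res)
  expect_true(all(c("quantity", "value", "unit") %in% names(td)))
})
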