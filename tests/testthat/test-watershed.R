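test_that("watershed splits an axially modulated channel into its chambers", {
  n <- 24; nz <- 78
  x <- (1:n) - 0.5; z <- (1:nz) - 0.5
  pore <- array(FALSE, c(n, n, nz))
  for (k in 1:nz) {
    r <- 3.5 * (1 + 0.35 * sin(2 * pi * z[k] / 13))
    pore[, , k] <- outer((x - 12)^2, (x - 12)^2, `+`) <= r^2
  }
  lab <- separate_objects(binary_microstructure(!pore, 1), "pore", h_maxima = 2)
  expect_identical(max(lab), 6L)            # 78 / 13 chambers
  expect_identical(sum(lab > 0), sum(pore)) # label conservation
})

test_that("h-maxima tolerance merges shallow maxima", {
  # two touching spheres with a wide neck: prominence above the saddle is
  # small, so a large h merges them into one object
  m <- sphere_mask(40, 9, c(14, 12, 12)) | sphere_mask(40, 9, c(26, 12, 12))
  b <- binary_microstructure(!m, 1)
  expect_identical(max(separate_objects(b, "pore", h_maxima = 1)), 2L)
  expect_identical(max(separate_objects(b, "pore", h_maxima = 8)), 1L)
})

test_that("a uniform slab yields a single object (flat plateau, one marker)", {
  slab <- generate_plate_phantom(c(24, 24, 24), 1, gap_um = 8, normal_axis = "z")
  lab <- separate_objects(slab, "pore", h_maxima = 2)
  expect_identical(max(lab), 1L)
})
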