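test_that("flow solutions and label volumes export as valid ASCII VTK", {
  dir <- withr::local_tempdir()
  pl <- generate_plate_phantom(c(12, 10, 12), 1, gap_um = 4, normal_axis = "z")
  sol <- solve_stokes_flow(pl, axis = "x", Q_m3_s = 1e-14)
  p <- file.path(dir, "flow.vtk")
  write_vtk_structured(sol, p)
  lines <- readLines(p)
  expect_identical(lines[3], "ASCII")
  expect_identical(lines[4], "DATASET STRUCTURED_POINTS")
  expect_identical(lines[5], "DIMENSIONS 12 10 12")
  expect_true(any(grepl("SCALARS pressure_Pa", lines)))
  expect_true(any(grepl("VECTORS velocity_m_per_s", lines)))
  # point count matches the declared dimensions
  i <- which(grepl("^LOOKUP_TABLE", lines))
  expect_equal(sum(!is.na(suppressWarnings(as.numeric(
    lines[(i + 1):(i + prod(dim(pl)))])))), prod(dim(pl)))
  # labels export
  lab <- separate_objects(pl, "pore")
  pl2 <- file.path(dir, "labels.vtk")
  write_vtk_structured(lab, pl2, name = "label")
  expect_true(any(grepl("SCALARS label", readLines(pl2))))
})

test_that("reports serialize to JSON with provenance", {
  dir <- withr::local_tempdir()
  cfg <- pipeline_config(
    synthetic = phantom_spec(shape = c(24, 24, 24), tube_radius_mean_um = 3,
                             seed = 2),
    morphometry = list(phases = "pore", axes = "z"),
    permeability = NULL, mechanics = NULL, seed = 2
  )
  rep <- suppressWarnings(run_pipeline(cfg, quiet = TRUE))
  p <- file.path(dir, "report.json")
  write_report_json(rep, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_identical(back$provenance$config_hash, rep$provenance$config_hash)
  expect_true("porosity" %in% back$values$quantity)
})
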