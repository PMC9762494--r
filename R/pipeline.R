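#' Pipeline configuration
#'
#' Assembles and validates the configuration of an end-to-end
#' characterization run. Exactly one input source must be given: a
#' synthetic phantom spec, or the path of a segmented binary TIFF volume,
#' or the path of a grayscale TIFF stack (which is then smoothed,
#' calibrated/thresholded and cropped per the segmentation settings).
#'
#' @param synthetic a [phantom_spec()], or `NULL`.
#' @param binary_path path to a binary TIFF + sidecar, or `NULL`.
#' @param grayscale_path path to a grayscale TIFF + sidecar, or `NULL`.
#' @param segmentation list: `tv` (fixed threshold), or `target_rate` for
#'   calibration, or neither for the histogram-minimum threshold;
#'   `smooth_radius` (default 1); optional `roi` = list(origin, edge).
#' @param morphometry list or `NULL` to skip: `h_maxima`, `connectivity`,
#'   `axes`, `phases`.
#' @param permeability list or `NULL` to skip: `axis`, `Q_m3_s`, `fluid`,
#'   `inlet`, `lateral`.
#' @param mechanics list or `NULL` to skip: `curve` (data frame; defaults
#'   to a synthetic J-curve), `models`, `target_E_MPa` (calibrates the
#'   solid modulus; defaults to the detected linear modulus), `poisson`,
#'   `homogenize` (logical), `homogenize_axes`, `homogenize_edge`
#'   (central RVE cube edge for the stiffness solve, default 32 voxels).
#' @param seed integer seed for any stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = phantom_spec(),
                            binary_path = NULL,
                            grayscale_path = NULL,
                            segmentation = list(),
                            morphometry = list(),
                            permeability = list(),
                            mechanics = list(),
                            seed = 1L) {
  sources <- !c(is.null(synthetic), is.null(binary_path), is.null(grayscale_path))
  if (sum(sources) != 1) {
    stop("exactly one input source (synthetic, binary_path, grayscale_path) is required",
         call. = FALSE)
  }
  for (p in c(binary_path, grayscale_path)) {
    if (!file.exists(p)) stop("input file does not exist: ", p, call. = FALSE)
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "phantom_spec"))
  structure(list(
    synthetic = synthetic, binary_path = binary_path,
    grayscale_path = grayscale_path,
    segmentation = segmentation, morphometry = morphometry,
    permeability = permeability, mechanics = mechanics,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the end-to-end characterization pipeline
#'
#' Executes the configured stages in order — input acquisition,
#' segmentation (for grayscale input), morphometry, image-based
#' permeability, mechanics (curve analysis, constitutive model selection,
#' solid-modulus calibration and directional homogenization) — and
#' collects a consolidated report. Stages configured as `NULL` are
#' skipped. The same configuration and seed always reproduce the same
#' report (iterative solvers to their stated tolerances).
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return A list of class `characterization_report`: `binary` (the
#'   characterized volume), `segmentation`, `morphometry`, `permeability`,
#'   `mechanics`, and `provenance` (config hash, seed, package version).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  report <- list(provenance = list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("poromech"))
  ))
  stage <- "input"
  result <- tryCatch({
    seg_info <- NULL
    if (!is.null(config$synthetic)) {
      say("stage input: generating synthetic phantom")
      binary <- generate_fiber_phantom(config$synthetic)
    } else if (!is.null(config$binary_path)) {
      say("stage input: reading binary volume %s", config$binary_path)
      binary <- read_volume_tiff(config$binary_path)
      if (!inherits(binary, "binary_microstructure")) {
        stop("binary_path does not contain a binary volume")
      }
    } else {
      stage <- "segmentation"
      say("stage segmentation: reading grayscale stack %s", config$grayscale_path)
      gray <- read_volume_tiff(config$grayscale_path)
      sgc <- config$segmentation
      r <- sgc[["smooth_radius"]] %||% 1L
      if (r > 0) gray <- mean_filter_smooth(gray, r)
      if (!is.null(sgc[["roi"]])) gray <- crop_cubic_roi(gray, sgc[["roi"]][["origin"]], sgc[["roi"]][["edge"]])
      if (!is.null(sgc[["tv"]])) {
        tv <- sgc[["tv"]]
      } else if (!is.null(sgc[["target_rate"]])) {
        cal <- calibrate_threshold_to_area_rate(gray, sgc[["target_rate"]])
        seg_info <- cal
        tv <- cal$chosen_tv
      } else {
        tv <- histogram_minimum_threshold(gray)
      }
      say("stage segmentation: threshold %g", tv)
      binary <- segment_by_threshold(gray, tv)
    }
    report$binary <- binary
    report$segmentation <- seg_info

    if (!is.null(config$morphometry)) {
      stage <- "morphometry"
      say("stage morphometry")
      mc <- config$morphometry
      report$morphometry <- morphometry(
        binary,
        axes = mc[["axes"]] %||% c("x", "y", "z"),
        phases = mc[["phases"]] %||% c("pore", "solid"),
        h_maxima = mc[["h_maxima"]] %||% 2,
        connectivity = mc[["connectivity"]] %||% 26
      )
    }

    if (!is.null(config$permeability)) {
      stage <- "permeability"
      pc <- config$permeability
      ax <- pc[["axis"]] %||% "z"
      say("stage permeability: axis %s", ax)
      sol <- solve_stokes_flow(
        binary, axis = ax, Q_m3_s = pc[["Q_m3_s"]] %||% 1e-12,
        fluid = pc[["fluid"]] %||% fluid_properties(),
        inlet = pc[["inlet"]] %||% "pressure",
        lateral = pc[["lateral"]] %||% "noslip"
      )
      d_char <- if (!is.null(report$morphometry) && !is.null(report$morphometry$pore_size)) {
        report$morphometry$pore_size$mean_um * 1e-6
      } else NULL
      report$permeability <- darcy_permeability(sol, characteristic_length_m = d_char)
      report$flow <- sol
    }

    if (!is.null(config$mechanics)) {
      stage <- "mechanics"
      say("stage mechanics")
      mech <- config$mechanics
      curve <- mech[["curve"]] %||% generate_stress_strain(curve_spec(
        linear_modulus_MPa = 38.5, toe_strain = 0.13,
        max_strain = 0.4, n_points = 120L, seed = config$seed
      ))
      lin <- linear_region_modulus(curve)
      selection <- select_best_model(
        curve, mech[["models"]] %||% c("yeoh3", "mooney_rivlin", "ogden1", "neo_hookean")
      )
      out <- list(linear_region = lin, model_selection = selection)
      if (isTRUE(mech[["homogenize"]] %||% TRUE)) {
        target <- mech[["target_E_MPa"]] %||% lin$modulus_MPa
        poisson <- mech[["poisson"]] %||% 0.49
        # stiffness runs on a central RVE cube: the direct sparse solve
        # scales steeply with edge length, and a converged porosity RVE
        # carries the effective-modulus information
        edge <- min(mech[["homogenize_edge"]] %||% 32L, dim(binary))
        hvol <- binary
        if (any(dim(binary) > edge)) {
          origin <- pmax((dim(binary) - edge) %/% 2L, 1L)
          hvol <- crop_cubic_roi(binary, origin, edge)
        }
        sm <- calibrate_solid_modulus(hvol, target, axis = "z", poisson = poisson)
        out$solid_modulus_MPa <- as.numeric(sm)
        out$homogenization <- homogenize_effective_moduli(
          hvol, as.numeric(sm), poisson,
          axes = mech[["homogenize_axes"]] %||% c("x", "y", "z")
        )
      }
      report$mechanics <- out
    }
    report
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  structure(result, class = "characterization_report")
}

#' @export
print.characterization_report <- function(x, ...) {
  cat("<characterization_report>\n")
  cat(sprintf("  config %s, seed %d\n", substr(x$provenance$config_hash, 1, 8),
              x$provenance$seed))
  if (!is.null(x$binary)) {
    cat(sprintf("  volume: %s voxels at %g um\n",
                paste(dim(x$binary), collapse = "x"), voxel_size(x$binary)))
  }
  if (!is.null(x$morphometry)) print(x$morphometry)
  if (!is.null(x$permeability)) {
    cat(sprintf("  permeability k = %.3e m^2 (dP = %.3e Pa)\n",
                x$permeability$k_m2, x$permeability$dP_Pa))
  }
  if (!is.null(x$mechanics)) {
    print(x$mechanics$linear_region)
    if (!is.null(x$mechanics$homogenization)) print(x$mechanics$homogenization)
  }
  invisible(x)
}
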