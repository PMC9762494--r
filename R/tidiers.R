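#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a hyperelastic fit
#'
#' @param x a [fit_hyperelastic()] result.
#' @param ... unused.
#' @return One row per coefficient: `term`, `estimate`.
#' @export
tidy.hyperelastic_fit <- function(x, ...) {
  cf <- unlist(x$params$coefficients)
  tibble::tibble(term = names(cf), estimate = unname(cf))
}

#' @rdname tidy.hyperelastic_fit
#' @return `glance()`: one row with `model`, `n_params`, `mse`, `stable`,
#'   `n`, and the small-strain Young's modulus `E0_MPa`.
#' @export
glance.hyperelastic_fit <- function(x, ...) {
  cf <- x$params$coefficients
  E0 <- switch(x$model_name,
    yeoh3 = 6 * cf$C10,
    neo_hookean = 6 * cf$C10,
    mooney_rivlin = 6 * (cf$C10 + cf$C01),
    ogden1 = 3 * cf$mu1
  )
  tibble::tibble(model = x$model_name, n_params = n_coefficients(x$model_name),
                 mse = x$fit_mse, stable = x$stable, n = x$n, E0_MPa = E0)
}

#' Tidy a model-selection ranking
#'
#' @param x a [select_best_model()] result.
#' @param ... unused.
#' @export
tidy.model_selection <- function(x, ...) x$ranking

#' Tidy a homogenization result
#'
#' @param x a [homogenize_effective_moduli()] result.
#' @param ... unused.
#' @return One row per axis: `axis`, `E_MPa`, `relative` (to the solid
#'   modulus).
#' @export
tidy.homogenization_result <- function(x, ...) {
  tibble::tibble(axis = names(x$E_MPa), E_MPa = unname(x$E_MPa),
                 relative = unname(x$E_MPa) / x$solid_modulus_MPa)
}

#' @rdname tidy.homogenization_result
#' @export
glance.homogenization_result <- function(x, ...) {
  tibble::tibble(solid_modulus_MPa = x$solid_modulus_MPa, poisson = x$poisson,
                 anisotropy_ratio = x$anisotropy_ratio)
}

#' Tidy a morphometry result
#'
#' @param x a [morphometry()] result.
#' @param ... unused.
#' @return Long tibble of scalar descriptors: `quantity`, `phase`, `axis`,
#'   `value`, `unit`.
#' @export
tidy.morphometry_result <- function(x, ...) {
  rows <- list(
    tibble::tibble(quantity = "porosity", phase = "pore", axis = NA_character_,
                   value = x$porosity, unit = "1"),
    tibble::tibble(quantity = "savr", phase = "solid", axis = NA_character_,
                   value = x$savr_um_inv, unit = "um^-1"),
    tibble::tibble(quantity = "savr_face_count", phase = "solid",
                   axis = NA_character_,
                   value = x$savr_face_count_um_inv, unit = "um^-1")
  )
  if (!is.null(x$tortuosity)) {
    rows$tau <- dplyr::transmute(
      x$tortuosity, quantity = "tortuosity", phase = .data$phase,
      axis = .data$axis, value = .data$tau, unit = "1"
    )
  }
  if (!is.null(x$pore_size)) {
    rows$ps <- tibble::tibble(
      quantity = c("pore_esd_mean", "pore_esd_sd"), phase = "pore",
      axis = NA_character_,
      value = c(x$pore_size$mean_um, x$pore_size$sd_um), unit = "um"
    )
  }
  if (!is.null(x$solid_thickness)) {
    rows$st <- tibble::tibble(
      quantity = c("solid_esd_mean", "solid_esd_sd"), phase = "solid",
      axis = NA_character_,
      value = c(x$solid_thickness$mean_um, x$solid_thickness$sd_um), unit = "um"
    )
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidy.morphometry_result
#' @export
glance.morphometry_result <- function(x, ...) {
  tibble::tibble(
    porosity = x$porosity, savr_um_inv = x$savr_um_inv,
    pore_esd_mean_um = if (!is.null(x$pore_size)) x$pore_size$mean_um else NA_real_,
    solid_esd_mean_um = if (!is.null(x$solid_thickness)) x$solid_thickness$mean_um else NA_real_,
    voxel_size_um = x$voxel_size_um
  )
}

#' Tidy a permeability result
#'
#' @param x a [darcy_permeability()] result.
#' @param ... unused.
#' @export
tidy.permeability_result <- function(x, ...) tibble::as_tibble(unclass(x))

#' Tidy a characterization report
#'
#' Stacks the scalar outputs of all executed stages into one long tibble.
#'
#' @param x a [run_pipeline()] report.
#' @param ... unused.
#' @export
tidy.characterization_report <- function(x, ...) {
  rows <- list()
  if (!is.null(x$morphometry)) {
    rows$morph <- dplyr::mutate(tidy(x$morphometry), stage = "morphometry")
  }
  if (!is.null(x$permeability)) {
    rows$perm <- tibble::tibble(
      stage = "permeability",
      quantity = c("k", "dP", "Re"), phase = NA_character_, axis = NA_character_,
      value = c(x$permeability$k_m2, x$permeability$dP_Pa, x$permeability$Re),
      unit = c("m^2", "Pa", "1")
    )
  }
  if (!is.null(x$mechanics)) {
    rows$mech <- tibble::tibble(
      stage = "mechanics",
      quantity = c("linear_modulus", "toe_strain"),
      phase = NA_character_, axis = NA_character_,
      value = c(x$mechanics$linear_region$modulus_MPa,
                x$mechanics$linear_region$toe_strain),
      unit = c("MPa", "1")
    )
    if (!is.null(x$mechanics$homogenization)) {
      rows$hom <- dplyr::mutate(
        dplyr::transmute(tidy(x$mechanics$homogenization),
                         quantity = paste0("E_", .data$axis),
                         phase = NA_character_, axis = .data$axis,
                         value = .data$E_MPa, unit = "MPa"),
        stage = "mechanics"
      )
    }
  }
  dplyr::bind_rows(rows)
}
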