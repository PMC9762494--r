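#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a threshold-calibration curve
#'
#' Solid-area rate against candidate threshold, with the target rate and
#' the chosen threshold highlighted.
#'
#' @param object a [calibrate_threshold_to_area_rate()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.calibration_result <- function(object, ...) {
  ggplot2::ggplot(object$area_rate_by_tv, ggplot2::aes(.data$tv, .data$area_rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$target_rate, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$chosen_tv, colour = "red") +
    ggplot2::labs(x = "threshold (grayscale)", y = "solid-area rate",
                  title = sprintf("chosen threshold %g", object$chosen_tv)) +
    ggplot2::theme_minimal()
}

#' Plot a hyperelastic fit over the data
#'
#' @param object a [fit_hyperelastic()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.hyperelastic_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted, ggplot2::aes(.data$stretch - 1)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$stress_MPa), alpha = 0.5, size = 0.9) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "engineering strain", y = "nominal stress (MPa)",
                  title = sprintf("%s fit (MSE %.3g MPa^2)",
                                  object$model_name, object$fit_mse)) +
    ggplot2::theme_minimal()
}

#' Plot an object-size (ESD) histogram
#'
#' @param object an [esd_distribution()] result.
#' @param bins histogram bin count.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.esd_distribution <- function(object, bins = 20, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(.data$esd_um)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean_um, linetype = 2) +
    ggplot2::labs(x = "equivalent spherical diameter (um)", y = "objects",
                  title = sprintf("ESD %.1f +/- %.1f um (n = %d)",
                                  object$mean_um, object$sd_um, object$n_objects)) +
    ggplot2::theme_minimal()
}

#' Plot the RVE-convergence table
#'
#' @param object an [assess_rve_convergence()] report.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.rve_report <- function(object, ...) {
  p <- ggplot2::ggplot(object$table, ggplot2::aes(.data$edge, .data$mean_porosity)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_porosity - .data$sd_porosity,
                                      ymax = .data$mean_porosity + .data$sd_porosity),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "sub-cube edge (voxels)", y = "porosity") +
    ggplot2::theme_minimal()
  if (!is.na(object$recommended_edge)) {
    p <- p + ggplot2::geom_vline(xintercept = object$recommended_edge,
                                 colour = "red", linetype = 2)
  }
  p
}

#' Plot the axial pressure profile of a flow solution
#'
#' Layer-averaged pressure along the flow axis; linear for a homogeneous
#' resistance, with deviations marking constrictions.
#'
#' @param sol a [solve_stokes_flow()] result.
#' @return A ggplot.
#' @export
plot_pressure_profile <- function(sol) {
  stopifnot(inherits(sol, "flow_solution"))
  ai <- axis_index(sol$axis)
  pr <- apply(sol$pressure, ai, mean, na.rm = TRUE)
  df <- tibble::tibble(
    position_um = (seq_along(pr) - 0.5) * sol$voxel_size_um,
    pressure_Pa = pr
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$position_um, .data$pressure_Pa)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.7) +
    ggplot2::labs(x = sprintf("position along %s (um)", sol$axis),
                  y = "layer-mean pressure (Pa)") +
    ggplot2::theme_minimal()
}

#' Plot a mid-stack slice of a volume
#'
#' @param vol a `voxel_volume`.
#' @param slice slice index along z (default: middle).
#' @return A ggplot raster of the slice.
#' @export
plot_slice <- function(vol, slice = NULL) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol)
  slice <- slice %||% ((d[3] + 1L) %/% 2L)
  sl <- vol[, , slice]
  df <- tidyr::expand_grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.numeric(sl[cbind(df$x, df$y)])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("slice z = %d", slice)) +
    ggplot2::theme_void()
}
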