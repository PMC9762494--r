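#' Voxel volume containers
#'
#' A `voxel_volume` is a plain 3D numeric/integer/logical array carrying a
#' physical voxel edge length (micrometres) and an axis-order tag. Two
#' flavours are used throughout the package:
#'
#' * `grayscale_volume`: integer-valued scalar image (raw stack input).
#' * `binary_microstructure`: two-phase volume where `TRUE`/`1` is the solid
#'   phase (tissue / scaffold wall) and `FALSE`/`0` is the pore phase.
#'
#' Axis ids are `"x"`, `"y"`, `"z"` mapping to array dimensions 1, 2, 3.
#'
#' @param values 3D array.
#' @param voxel_size_um voxel edge length in micrometres (> 0).
#' @param threshold_used optional provenance: grayscale threshold that
#'   produced a binary volume.
#' @return An object of class `grayscale_volume` or `binary_microstructure`
#'   (both inherit `voxel_volume`), a 3D array with attributes
#'   `voxel_size_um` and `axes` (`"xyz"`).
#' @examples
#' b <- binary_microstructure(array(c(TRUE, FALSE), c(2, 2, 2)), voxel_size_um = 3)
#' voxel_size(b)
#' @export
grayscale_volume <- function(values, voxel_size_um) {
  check_volume_args(values, voxel_size_um)
  structure(values,
    voxel_size_um = voxel_size_um, axes = "xyz",
    class = c("grayscale_volume", "voxel_volume")
  )
}

#' @rdname grayscale_volume
#' @export
binary_microstructure <- function(values, voxel_size_um, threshold_used = NULL) {
  check_volume_args(values, voxel_size_um)
  u <- unique(as.vector(values))
  if (!all(u %in% c(0, 1, TRUE, FALSE))) {
    stop("binary_microstructure requires exactly two phase labels (0/1)", call. = FALSE)
  }
  v <- array(as.logical(values), dim(values))
  structure(v,
    voxel_size_um = voxel_size_um, axes = "xyz",
    threshold_used = threshold_used,
    class = c("binary_microstructure", "voxel_volume")
  )
}

check_volume_args <- function(values, voxel_size_um) {
  if (!is.array(values) || length(dim(values)) != 3) {
    stop("`values` must be a 3D array", call. = FALSE)
  }
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1 || voxel_size_um <= 0) {
    stop("`voxel_size_um` must be a single positive number", call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname grayscale_volume
#' @param vol a `voxel_volume`.
#' @export
voxel_size <- function(vol) attr(vol, "voxel_size_um")

#' Solid-phase mask of a binary microstructure
#'
#' @param binary a `binary_microstructure`.
#' @return Logical 3D array, `TRUE` on the solid phase.
#' @keywords internal
solid_mask <- function(binary) {
  stopifnot(inherits(binary, "binary_microstructure"))
  array(as.logical(binary), dim(binary))
}

#' Pore-phase mask of a binary microstructure
#' @inheritParams solid_mask
#' @keywords internal
pore_mask <- function(binary) !solid_mask(binary)

phase_mask <- function(binary, phase = c("pore", "solid")) {
  phase <- match.arg(phase)
  if (phase == "solid") solid_mask(binary) else pore_mask(binary)
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<%s> %d x %d x %d voxels, voxel size %g um\n",
    class(x)[1], d[1], d[2], d[3], voxel_size(x)
  ))
  if (inherits(x, "binary_microstructure")) {
    cat(sprintf("  solid fraction %.4f", mean(x)))
    tv <- attr(x, "threshold_used")
    if (!is.null(tv)) cat(sprintf("  (threshold %g)", tv))
    cat("\n")
  } else {
    cat(sprintf("  range [%g, %g]\n", min(x), max(x)))
  }
  invisible(x)
}

#' Map an axis id to an array dimension index
#' @param axis one of `"x"`, `"y"`, `"z"` (or 1, 2, 3).
#' @return Integer dimension index.
#' @keywords internal
axis_index <- function(axis) {
  if (is.numeric(axis) && axis %in% 1:3) return(as.integer(axis))
  i <- match(tolower(as.character(axis)), c("x", "y", "z"))
  if (is.na(i)) stop("`axis` must be one of 'x', 'y', 'z'", call. = FALSE)
  i
}
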