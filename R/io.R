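#' Read and write voxel volumes as multi-page TIFF with a JSON sidecar
#'
#' Volumes are stored as multi-page 8-bit TIFF (one page per z-slice,
#' grayscale 0-255; binary volumes use 0/255) together with a JSON sidecar
#' `<file>.json` recording `voxel_size_um`, the axis order (`"xyz"`, pages
#' along z) and the phase encoding of binary volumes.
#'
#' @param vol a `voxel_volume`.
#' @param path TIFF file path (sidecar written next to it).
#' @return `write_volume_tiff()` returns `path` invisibly;
#'   `read_volume_tiff()` returns a [grayscale_volume()] or
#'   [binary_microstructure()] according to the sidecar.
#' @export
write_volume_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  is_bin <- inherits(vol, "binary_microstructure")
  d <- dim(vol)
  pages <- lapply(seq_len(d[3]), function(k) {
    sl <- vol[, , k]
    v <- if (is_bin) ifelse(sl, 255, 0) else pmin(pmax(as.numeric(sl), 0), 255)
    # tiff expects values in [0,1]; transpose so rows are the y dimension
    t(matrix(v / 255, d[1], d[2]))
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  sidecar <- list(
    voxel_size_um = voxel_size(vol), axes = "xyz", pages = "z",
    kind = if (is_bin) "binary" else "grayscale",
    phase_encoding = if (is_bin) "solid=255, pore=0" else NULL,
    threshold_used = attr(vol, "threshold_used")
  )
  jsonlite::write_json(sidecar[!vapply(sidecar, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @param path TIFF file path; `<path>.json` must exist.
#' @export
read_volume_tiff <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop("missing JSON sidecar: ", side_path, call. = FALSE)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d12 <- dim(pages[[1]])[2:1]
  a <- array(0, c(d12, length(pages)))
  for (k in seq_along(pages)) a[, , k] <- t(pages[[k]]) * 255
  if (identical(side$kind, "binary")) {
    binary_microstructure(a > 127, side$voxel_size_um,
                          threshold_used = side$threshold_used)
  } else {
    grayscale_volume(array(as.integer(round(a)), dim(a)), side$voxel_size_um)
  }
}

#' Read and write uniaxial curves and falling-head records as CSV
#'
#' Curves use columns `stretch` (or `strain`) and `stress_MPa`;
#' falling-head records use columns `a_m2, A_m2, H_m, L1_m, L2_m, t_s`
#' (plus optional `sample`).
#'
#' @param curve,test tibbles to write.
#' @param path CSV path.
#' @return Readers return tibbles of class `stress_strain_curve` /
#'   `falling_head_test`.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as_curve_tibble(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  out <- as_curve_tibble(out)
  class(out) <- c("stress_strain_curve", class(out))
  out
}

#' @rdname write_curve_csv
#' @export
write_falling_head_csv <- function(test, path) {
  utils::write.csv(test, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_falling_head_csv <- function(path) {
  df <- utils::read.csv(path)
  falling_head_test(
    a_m2 = df$a_m2, A_m2 = df$A_m2, H_m = df$H_m,
    L1_m = df$L1_m, L2_m = df$L2_m, t_s = df$t_s,
    sample = if ("sample" %in% names(df)) df$sample else NA_character_
  )
}
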