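#' Mean-filter smoothing of a grayscale volume
#'
#' Replaces each voxel by the mean of its cubic neighbourhood of half-width
#' `radius`. At the volume boundary the neighbourhood is clipped (shrinks);
#' no padding values are invented, so boundary slices are not biased toward
#' any fill level.
#'
#' @param gray a [grayscale_volume()].
#' @param radius integer >= 0, neighbourhood half-width in voxels.
#' @return A smoothed [grayscale_volume()] (numeric values).
#' @export
mean_filter_smooth <- function(gray, radius = 1L) {
  stopifnot(inherits(gray, "grayscale_volume"))
  radius <- as.integer(radius)
  stopifnot(radius >= 0)
  if (radius == 0) return(gray)
  a <- array(as.numeric(gray), dim(gray))
  s <- a
  cnt <- array(1, dim(a))
  for (d in 1:3) {
    s <- box_sum_1d(s, d, radius)
    cnt <- box_sum_1d(cnt, d, radius)
  }
  grayscale_volume(s / cnt, voxel_size(gray))
}

#' Threshold a grayscale volume into a two-phase microstructure
#'
#' Voxels with grayscale value strictly greater than `tv` are labelled
#' solid (tissue); values `<= tv` become pore. The threshold is recorded in
#' the result's provenance.
#'
#' @param gray a [grayscale_volume()].
#' @param tv grayscale threshold.
#' @return A [binary_microstructure()] with `threshold_used` set.
#' @export
segment_by_threshold <- function(gray, tv) {
  stopifnot(inherits(gray, "grayscale_volume"), is.numeric(tv), length(tv) == 1)
  binary_microstructure(array(gray > tv, dim(gray)), voxel_size(gray),
                        threshold_used = tv)
}

#' Histogram-minimum threshold
#'
#' Finds the grayscale value at the minimum of the (moving-average smoothed)
#' histogram, strictly between its two highest distinct modes. Ties are
#' broken toward the lower bin. Errors on unimodal histograms, where a
#' manual threshold is required instead.
#'
#' @param gray a [grayscale_volume()].
#' @param smooth_width moving-average width (bins) applied before peak
#'   finding; default 5.
#' @return The threshold grayscale value (scalar).
#' @export
histogram_minimum_threshold <- function(gray, smooth_width = 5L) {
  stopifnot(inherits(gray, "grayscale_volume"))
  v <- as.integer(round(as.vector(gray)))
  rng <- range(v)
  if (rng[1] == rng[2]) stop("histogram is unimodal (constant image); supply a manual threshold",
                             call. = FALSE)
  bins <- rng[1]:rng[2]
  counts <- tabulate(v - rng[1] + 1L, nbins = length(bins))
  sm <- stats::filter(counts, rep(1 / smooth_width, smooth_width), sides = 2)
  sm <- as.numeric(sm)
  # clipped moving average at the ends
  na <- is.na(sm)
  if (any(na)) {
    half <- smooth_width %/% 2
    for (i in which(na)) {
      lo <- max(1, i - half); hi <- min(length(counts), i + half)
      sm[i] <- mean(counts[lo:hi])
    }
  }
  # local maxima of the smoothed histogram (plateau-aware)
  n <- length(sm)
  is_max <- vapply(seq_len(n), function(i) {
    l <- if (i > 1) sm[i - 1] else -Inf
    r <- if (i < n) sm[i + 1] else -Inf
    sm[i] > l && sm[i] >= r
  }, logical(1))
  peaks <- which(is_max)
  peaks <- peaks[order(sm[peaks], decreasing = TRUE)]
  if (length(peaks) < 2) {
    stop("histogram is unimodal; supply a manual threshold", call. = FALSE)
  }
  # second mode: the highest peak separated from the first by a genuine
  # valley (smoothed count dipping below 80% of the smaller peak), so a
  # shoulder bump on the main mode is never mistaken for a second mode
  p1 <- peaks[1]
  p2 <- NA_integer_
  for (cand in peaks[-1]) {
    if (abs(bins[cand] - bins[p1]) <= smooth_width) next
    between <- (min(p1, cand) + 1):(max(p1, cand) - 1)
    if (length(between) && min(sm[between]) <= 0.8 * sm[cand]) {
      p2 <- cand
      break
    }
  }
  if (is.na(p2)) stop("histogram is unimodal; supply a manual threshold", call. = FALSE)
  lo <- min(p1, p2); hi <- max(p1, p2)
  valley <- (lo + 1):(hi - 1)
  if (length(valley) == 0) stop("no valley between the histogram modes", call. = FALSE)
  # minimum of the raw counts in the valley, ties toward the lower bin
  bins[valley[which.min(counts[valley])]]
}

#' Calibrate the segmentation threshold against a histology area rate
#'
#' For every candidate threshold, segments the stack and computes the mean
#' per-slice solid-area fraction ("surface area rate", the 2D solid-pixel
#' fraction of each transverse slice averaged over slices). The chosen
#' threshold minimizes the absolute deviation from `target_rate` — the
#' solid-area fraction measured on a matched histological section.
#'
#' @param gray a [grayscale_volume()].
#' @param target_rate target solid-area fraction in (0, 1).
#' @param tv_candidates numeric vector of thresholds to scan (default: the
#'   full observed grayscale range).
#' @param slice_axis axis normal to the "slices" (default `"z"`).
#' @return A list of class `calibration_result`: `chosen_tv`, `target_rate`,
#'   and `area_rate_by_tv` (tibble of `tv`, `area_rate`).
#' @export
calibrate_threshold_to_area_rate <- function(gray, target_rate,
                                             tv_candidates = NULL,
                                             slice_axis = "z") {
  stopifnot(inherits(gray, "grayscale_volume"))
  if (!(target_rate >= 0 && target_rate <= 1)) {
    stop("`target_rate` must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(tv_candidates)) {
    rng <- range(as.vector(gray))
    tv_candidates <- seq(floor(rng[1]) - 1, ceiling(rng[2]))
  }
  stopifnot(length(tv_candidates) >= 1)
  rate <- vapply(tv_candidates, function(tv) {
    solid_area_rate(gray, tv, slice_axis)
  }, numeric(1))
  dev <- abs(rate - target_rate)
  # ties broken toward the lower threshold (which.min takes the first)
  chosen <- tv_candidates[which.min(dev)]
  structure(list(
    chosen_tv = chosen,
    target_rate = target_rate,
    area_rate_by_tv = tibble::tibble(tv = tv_candidates, area_rate = rate)
  ), class = "calibration_result")
}

# mean per-slice solid-pixel fraction at threshold tv
solid_area_rate <- function(gray, tv, slice_axis = "z") {
  ai <- axis_index(slice_axis)
  solid <- gray > tv
  per_slice <- apply(solid, ai, mean)
  mean(per_slice)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> chosen threshold %g (target area rate %.4f, achieved %.4f)\n",
    x$chosen_tv, x$target_rate,
    x$area_rate_by_tv$area_rate[match(x$chosen_tv, x$area_rate_by_tv$tv)]
  ))
  invisible(x)
}

#' Crop a cubic region of interest
#'
#' @param vol a `voxel_volume`.
#' @param origin integer triple, 1-based corner voxel of the ROI.
#' @param edge cube edge length in voxels.
#' @return The cropped volume (same class, voxel size preserved).
#' @export
crop_cubic_roi <- function(vol, origin, edge) {
  stopifnot(inherits(vol, "voxel_volume"))
  origin <- as.integer(origin); edge <- as.integer(edge)
  stopifnot(length(origin) == 3, edge >= 1)
  hi <- origin + edge - 1L
  d <- dim(vol)
  for (ax in 1:3) {
    if (origin[ax] < 1 || hi[ax] > d[ax]) {
      stop(sprintf("ROI exceeds volume bounds along axis %s (need [%d, %d] within [1, %d])",
                   c("x", "y", "z")[ax], origin[ax], hi[ax], d[ax]), call. = FALSE)
    }
  }
  out <- vol[origin[1]:hi[1], origin[2]:hi[2], origin[3]:hi[3], drop = FALSE]
  if (inherits(vol, "binary_microstructure")) {
    binary_microstructure(out, voxel_size(vol), threshold_used = attr(vol, "threshold_used"))
  } else {
    grayscale_volume(out, voxel_size(vol))
  }
}

#' Assess representative-volume-element convergence by porosity
#'
#' For each candidate edge size, samples `n_positions` random sub-cubes and
#' records their porosity. The recommended RVE edge is the smallest whose
#' porosity SD is at most `sd_tol` and whose mean porosity is within
#' `mean_tol` of the largest edge's mean.
#'
#' @param binary a [binary_microstructure()].
#' @param edge_sizes integer vector of cube edges (voxels), each within the
#'   volume.
#' @param n_positions sub-cubes per edge size (>= 1).
#' @param seed RNG seed for sub-cube placement.
#' @param sd_tol,mean_tol convergence criteria (porosity units); defaults
#'   0.01 and 0.01.
#' @return A list of class `rve_report`: `table` (tibble of `edge`,
#'   `mean_porosity`, `sd_porosity`, `converged`), `recommended_edge`
#'   (NA if no edge satisfies the criterion) and the tolerances.
#' @export
assess_rve_convergence <- function(binary, edge_sizes, n_positions = 10L, seed = 1L,
                                   sd_tol = 0.01, mean_tol = 0.01) {
  stopifnot(inherits(binary, "binary_microstructure"), n_positions >= 1)
  d <- dim(binary)
  edge_sizes <- sort(as.integer(edge_sizes))
  if (max(edge_sizes) > min(d)) stop("largest edge exceeds the volume extent", call. = FALSE)
  pm <- pore_mask(binary)
  res <- with_seed(seed, {
    purrr::map_dfr(edge_sizes, function(e) {
      por <- vapply(seq_len(n_positions), function(i) {
        o <- vapply(1:3, function(ax) if (d[ax] == e) 1L else sample.int(d[ax] - e + 1L, 1L),
                    integer(1))
        mean(pm[o[1]:(o[1] + e - 1L), o[2]:(o[2] + e - 1L), o[3]:(o[3] + e - 1L)])
      }, numeric(1))
      tibble::tibble(
        edge = e,
        mean_porosity = mean(por),
        sd_porosity = if (length(por) > 1) stats::sd(por) else 0
      )
    })
  })
  ref <- res$mean_porosity[which.max(res$edge)]
  res$converged <- res$sd_porosity <= sd_tol & abs(res$mean_porosity - ref) <= mean_tol
  rec <- if (any(res$converged)) min(res$edge[res$converged]) else NA_integer_
  structure(list(
    table = res, recommended_edge = rec,
    sd_tol = sd_tol, mean_tol = mean_tol
  ), class = "rve_report")
}

#' @export
print.rve_report <- function(x, ...) {
  cat("<rve_report>\n")
  print(x$table)
  if (is.na(x$recommended_edge)) cat("not converged at the stated criterion\n")
  else cat(sprintf("recommended RVE edge: %d voxels\n", x$recommended_edge))
  invisible(x)
}
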