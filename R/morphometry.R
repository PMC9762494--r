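#' Porosity of a binary microstructure
#'
#' Pore-voxel count divided by total voxel count.
#'
#' @param binary a [binary_microstructure()].
#' @return Pore volume fraction in `[0, 1]`.
#' @export
compute_porosity <- function(binary) {
  stopifnot(inherits(binary, "binary_microstructure"))
  mean(pore_mask(binary))
}

#' Surface area-to-volume ratio (SAVR)
#'
#' Internal solid-pore interface area divided by the total volume, in
#' um^-1. The domain's outer boundary faces are excluded, so the measure
#' does not depend on where the ROI was cut.
#'
#' Two estimators are available: `"isosurface"` (default) triangulates the
#' 0.5 level set of the mean-filtered solid indicator by marching
#' tetrahedra, which converges to the true area of smooth interfaces;
#' `"face_count"` counts exposed voxel faces, a simple upper-bias oracle
#' (overestimates smooth oblique surfaces by up to ~1.5x).
#'
#' @param binary a [binary_microstructure()].
#' @param method `"isosurface"` or `"face_count"`.
#' @param smooth_radius mean-filter half-width (voxels) applied to the
#'   indicator before triangulation; 1 by default.
#' @return SAVR in um^-1 (0 with a warning if the solid phase is empty).
#' @export
compute_savr <- function(binary, method = c("isosurface", "face_count"),
                         smooth_radius = 1L) {
  stopifnot(inherits(binary, "binary_microstructure"))
  method <- match.arg(method)
  h <- voxel_size(binary)
  sm <- solid_mask(binary)
  vol_um3 <- prod(dim(binary)) * h^3
  if (!any(sm)) {
    warning("solid phase is empty; SAVR = 0", call. = FALSE)
    return(0)
  }
  if (method == "face_count") {
    area_vox <- 0
    for (d in 1:3) {
      a <- index_dim(sm, d, 1:(dim(sm)[d] - 1L))
      b <- index_dim(sm, d, 2:dim(sm)[d])
      area_vox <- area_vox + sum(a != b)   # interior faces only
    }
    return(area_vox * h^2 / vol_um3)
  }
  field <- array(as.numeric(sm), dim(sm))
  if (smooth_radius > 0) {
    s <- field; cnt <- array(1, dim(field))
    for (d in 1:3) {
      s <- box_sum_1d(s, d, smooth_radius)
      cnt <- box_sum_1d(cnt, d, smooth_radius)
    }
    field <- s / cnt
  }
  area_vox <- marching_tetrahedra_area(field, level = 0.5)
  area_vox * h^2 / vol_um3
}

#' Does a phase percolate between two opposite faces?
#'
#' @param binary a [binary_microstructure()].
#' @param phase `"pore"` or `"solid"`.
#' @param axis axis id.
#' @param connectivity 6 or 26 (default 26).
#' @return `TRUE` if a connected path of the phase joins the two faces
#'   normal to `axis`.
#' @export
phase_percolates <- function(binary, phase = "pore", axis = "z", connectivity = 26) {
  g <- phase_graph(binary, phase, connectivity)
  if (g$n == 0) return(FALSE)
  ai <- axis_index(axis)
  comp <- igraph::components(g$graph)$membership
  inlet <- comp[face_node_ids(dim(binary), ai, 1L, g$index_map)]
  outlet <- comp[face_node_ids(dim(binary), ai, dim(binary)[ai], g$index_map)]
  length(intersect(unique(inlet), unique(outlet))) > 0
}

# node ids of phase voxels on face `pos` normal to axis ai
face_node_ids <- function(d, ai, pos, index_map) {
  sl <- index_dim(index_map, ai, pos)
  as.vector(sl[sl > 0])
}

# Build the voxel adjacency graph of a phase. Returns the igraph object,
# node count, and an index map (3D array: 0 off-phase, node id on phase).
phase_graph <- function(binary, phase = "pore", connectivity = 26) {
  m <- phase_mask(binary, phase)
  d <- dim(m)
  n_nodes <- sum(m)
  index_map <- array(0L, d)
  index_map[m] <- seq_len(n_nodes)
  if (n_nodes == 0) return(list(graph = NULL, n = 0L, index_map = index_map))
  offs <- neighbor_offsets_26()
  if (connectivity == 6) {
    keep <- offs$lengths == 1
    offs$offsets <- offs$offsets[keep, , drop = FALSE]
    offs$lengths <- offs$lengths[keep]
  }
  # positive half of the neighbourhood (each undirected edge once)
  half <- which(
    offs$offsets[, 3] > 0 |
      (offs$offsets[, 3] == 0 & offs$offsets[, 2] > 0) |
      (offs$offsets[, 3] == 0 & offs$offsets[, 2] == 0 & offs$offsets[, 1] > 0)
  )
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in half) {
    o <- offs$offsets[r, ]
    sh <- shift3(index_map, 1L, o[1], 0L)
    if (o[2] != 0) sh <- shift3(sh, 2L, o[2], 0L)
    if (o[3] != 0) sh <- shift3(sh, 3L, o[3], 0L)
    # sh[v] holds the id of the voxel at v - o; pair with index_map[v]
    ok <- index_map > 0L & sh > 0L
    if (any(ok)) {
      from <- c(from, index_map[ok])
      to <- c(to, sh[ok])
      w <- c(w, rep(offs$lengths[r], sum(ok)))
    }
  }
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to), weight = w)
  }
  list(graph = g, n = n_nodes, index_map = index_map)
}

#' Geodesic tortuosity of a phase along an axis
#'
#' For every phase voxel on the inlet face that connects to the outlet
#' face, the geodesic shortest-path length to the opposite face is computed
#' on the 26-connected voxel graph with Euclidean edge weights, and divided
#' by the straight-line extent of the domain (centre-to-centre,
#' `(n - 1) * voxel_size`). The summary statistic is the mean over inlet
#' voxels of the percolating component; the minimum (single best path) is
#' also reported, as a noise-dominated lower bound.
#'
#' @param binary a [binary_microstructure()].
#' @param phase `"pore"` or `"solid"`.
#' @param axis axis id.
#' @param connectivity 6 or 26 (default 26; 6 exaggerates path lengths of
#'   oblique channels).
#' @return A list of class `tortuosity_result`: `tau` (mean), `tau_min`,
#'   `n_paths`, `percolating`, `phase`, `axis`. `tau` is `NA` when the
#'   phase does not percolate.
#' @export
compute_tortuosity <- function(binary, phase = "pore", axis = "z", connectivity = 26) {
  stopifnot(inherits(binary, "binary_microstructure"))
  ai <- axis_index(axis)
  d <- dim(binary)
  h <- voxel_size(binary)
  pg <- phase_graph(binary, phase, connectivity)
  out <- structure(list(
    tau = NA_real_, tau_min = NA_real_, n_paths = 0L,
    percolating = FALSE, phase = phase, axis = axis
  ), class = "tortuosity_result")
  if (pg$n == 0) return(out)
  inlet_ids <- face_node_ids(d, ai, 1L, pg$index_map)
  outlet_ids <- face_node_ids(d, ai, d[ai], pg$index_map)
  if (!length(inlet_ids) || !length(outlet_ids)) return(out)
  # virtual source glued to the outlet face with negligible-weight edges
  eps <- 1e-9
  g <- igraph::add_vertices(pg$graph, 1)
  src <- pg$n + 1L
  g <- igraph::add_edges(g, rbind(rep(src, length(outlet_ids)), outlet_ids),
                         weight = rep(eps, length(outlet_ids)))
  dmat <- igraph::distances(g, v = src, to = inlet_ids,
                            weights = igraph::E(g)$weight, algorithm = "dijkstra")
  dvox <- as.numeric(dmat) - eps
  fin <- is.finite(dvox)
  if (!any(fin)) return(out)
  extent <- (d[ai] - 1) * h
  tau_i <- (dvox[fin] * h) / extent
  out$tau <- mean(tau_i)
  out$tau_min <- min(tau_i)
  out$n_paths <- sum(fin)
  out$percolating <- TRUE
  out
}

#' @export
print.tortuosity_result <- function(x, ...) {
  if (!x$percolating) {
    cat(sprintf("<tortuosity> %s phase, axis %s: non-percolating\n", x$phase, x$axis))
  } else {
    cat(sprintf("<tortuosity> %s phase, axis %s: tau = %.4f (min %.4f, %d inlet paths)\n",
                x$phase, x$axis, x$tau, x$tau_min, x$n_paths))
  }
  invisible(x)
}

#' Separate a phase into objects by marker-based watershed
#'
#' Objects (pores or solid walls) are separated on the negated Euclidean
#' distance transform of the phase: catchment basins of the distance map,
#' flooded from its regional maxima after h-maxima suppression (the
#' `h_maxima` tolerance merges maxima shallower than `h`, suppressing
#' spurious splits from voxelization). Every phase voxel receives exactly
#' one label.
#'
#' @param binary a [binary_microstructure()].
#' @param phase `"pore"` or `"solid"`.
#' @param h_maxima depth tolerance (voxels) for watershed merging;
#'   default 2.
#' @return Integer 3D array of labels (0 = off phase), with attribute
#'   `voxel_size_um`.
#' @export
separate_objects <- function(binary, phase = "pore", h_maxima = 2) {
  stopifnot(inherits(binary, "binary_microstructure"))
  m <- phase_mask(binary, phase)
  if (!any(m)) stop("phase is empty", call. = FALSE)
  dt <- edt3(m)
  lab <- watershed3(dt, m, h = h_maxima)
  structure(lab, voxel_size_um = voxel_size(binary))
}

#' Equivalent spherical diameter distribution of separated objects
#'
#' Converts each object's voxel volume to the diameter of the
#' equal-volume sphere, `ESD = (6 V / pi)^(1/3)`.
#'
#' @param labeled integer label array from [separate_objects()].
#' @param voxel_size_um voxel edge (taken from the label array's attribute
#'   if absent).
#' @return A list of class `esd_distribution`: `table` (tibble of `label`,
#'   `n_voxels`, `volume_um3`, `esd_um`), `mean_um`, `sd_um`, `n_objects`.
#' @export
esd_distribution <- function(labeled, voxel_size_um = NULL) {
  voxel_size_um <- voxel_size_um %||% attr(labeled, "voxel_size_um")
  stopifnot(!is.null(voxel_size_um))
  counts <- tabulate(labeled[labeled > 0L])
  keep <- which(counts > 0)
  if (!length(keep)) stop("no objects in the label array", call. = FALSE)
  vol <- counts[keep] * voxel_size_um^3
  esd <- (6 * vol / pi)^(1 / 3)
  tab <- tibble::tibble(label = keep, n_voxels = counts[keep],
                        volume_um3 = vol, esd_um = esd)
  structure(list(
    table = tab, mean_um = mean(esd),
    sd_um = if (length(esd) > 1) stats::sd(esd) else 0,
    n_objects = length(esd)
  ), class = "esd_distribution")
}

#' @export
print.esd_distribution <- function(x, ...) {
  cat(sprintf("<esd_distribution> %d objects, ESD %.2f +/- %.2f um\n",
              x$n_objects, x$mean_um, x$sd_um))
  invisible(x)
}

#' Full microstructural morphometry of a binary volume
#'
#' Computes the standard descriptor set of a two-phase microstructure:
#' porosity, SAVR (isosurface estimate, with the face-counting oracle
#' reported alongside), per-phase per-axis geodesic tortuosity, and
#' watershed/ESD size distributions of both phases (pore size and solid
#' wall thickness).
#'
#' @param binary a [binary_microstructure()].
#' @param axes axes for tortuosity (default all three).
#' @param phases phases for tortuosity and sizing (default both).
#' @param h_maxima watershed merge tolerance, voxels.
#' @param connectivity voxel connectivity for tortuosity.
#' @param sizes,tortuosity logical switches to skip the expensive stages.
#' @return A list of class `morphometry_result` with elements `porosity`,
#'   `savr_um_inv`, `savr_face_count_um_inv`, `tortuosity` (tibble),
#'   `pore_size` and `solid_thickness` ([esd_distribution()] objects or
#'   `NULL`), `voxel_size_um`, `dim`.
#' @export
morphometry <- function(binary, axes = c("x", "y", "z"),
                        phases = c("pore", "solid"),
                        h_maxima = 2, connectivity = 26,
                        sizes = TRUE, tortuosity = TRUE) {
  stopifnot(inherits(binary, "binary_microstructure"))
  res <- list(
    porosity = compute_porosity(binary),
    savr_um_inv = compute_savr(binary, "isosurface"),
    savr_face_count_um_inv = compute_savr(binary, "face_count"),
    voxel_size_um = voxel_size(binary),
    dim = dim(binary)
  )
  if (tortuosity) {
    res$tortuosity <- purrr::map_dfr(phases, function(ph) {
      purrr::map_dfr(axes, function(ax) {
        t <- compute_tortuosity(binary, ph, ax, connectivity)
        tibble::tibble(phase = ph, axis = ax, tau = t$tau, tau_min = t$tau_min,
                       n_paths = t$n_paths, percolating = t$percolating)
      })
    })
  } else res$tortuosity <- NULL
  if (sizes) {
    res$pore_size <- if ("pore" %in% phases) {
      esd_distribution(separate_objects(binary, "pore", h_maxima))
    }
    res$solid_thickness <- if ("solid" %in% phases) {
      esd_distribution(separate_objects(binary, "solid", h_maxima))
    }
  }
  structure(res, class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat("<morphometry_result>\n")
  cat(sprintf("  porosity          %.4f\n", x$porosity))
  cat(sprintf("  SAVR              %.4f um^-1 (face-count %.4f)\n",
              x$savr_um_inv, x$savr_face_count_um_inv))
  if (!is.null(x$pore_size)) {
    cat(sprintf("  pore size         %.2f +/- %.2f um (%d objects)\n",
                x$pore_size$mean_um, x$pore_size$sd_um, x$pore_size$n_objects))
  }
  if (!is.null(x$solid_thickness)) {
    cat(sprintf("  solid thickness   %.2f +/- %.2f um (%d objects)\n",
                x$solid_thickness$mean_um, x$solid_thickness$sd_um,
                x$solid_thickness$n_objects))
  }
  if (!is.null(x$tortuosity)) {
    cat("  tortuosity:\n")
    print(x$tortuosity)
  }
  invisible(x)
}
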