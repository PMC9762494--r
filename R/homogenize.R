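# --- linear voxel (hexahedral) elasticity -----------------------------------

# 24x24 stiffness of a trilinear hexahedral element with edge h (um),
# isotropic (E, nu), full 2x2x2 Gauss integration. Scales linearly in E and
# in h, so it is computed once for E = 1 and rescaled.
hex_stiffness <- function(E, nu, h) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  g <- 1 / sqrt(3)
  gp <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
  signs <- as.matrix(expand.grid(sx = c(-1, 1), sy = c(-1, 1), sz = c(-1, 1)))
  K <- matrix(0, 24, 24)
  detJ <- (h / 2)^3
  for (q in seq_len(nrow(gp))) {
    xi <- gp[q, 1]; eta <- gp[q, 2]; zeta <- gp[q, 3]
    dN <- matrix(0, 8, 3)
    for (i in 1:8) {
      sx <- signs[i, 1]; sy <- signs[i, 2]; sz <- signs[i, 3]
      dN[i, 1] <- sx * (1 + sy * eta) * (1 + sz * zeta) / 8
      dN[i, 2] <- (1 + sx * xi) * sy * (1 + sz * zeta) / 8
      dN[i, 3] <- (1 + sx * xi) * (1 + sy * eta) * sz / 8
    }
    dN <- dN * (2 / h)   # natural -> physical derivatives
    B <- matrix(0, 6, 24)
    for (i in 1:8) {
      c0 <- 3 * (i - 1)
      B[1, c0 + 1] <- dN[i, 1]
      B[2, c0 + 2] <- dN[i, 2]
      B[3, c0 + 3] <- dN[i, 3]
      B[4, c0 + 1] <- dN[i, 2]; B[4, c0 + 2] <- dN[i, 1]
      B[5, c0 + 2] <- dN[i, 3]; B[5, c0 + 3] <- dN[i, 2]
      B[6, c0 + 1] <- dN[i, 3]; B[6, c0 + 3] <- dN[i, 1]
    }
    K <- K + t(B) %*% D %*% B * detJ
  }
  (K + t(K)) / 2
}

# Assemble the global stiffness of the solid voxels (trilinear hexahedra on
# the voxel lattice). Returns the sparse K over active dofs and index maps.
assemble_voxel_stiffness <- function(solid, h, E, nu, chunk = 20000L) {
  d <- dim(solid)
  nd <- d + 1L
  Ke <- hex_stiffness(E, nu, h)
  elem <- which(solid)
  ne <- length(elem)
  es <- arrayInd(elem, d)
  # grid node ids of the 8 corners, in cube_corner_offsets order
  corner <- cube_corner_offsets
  node_of <- function(ii, jj, kk) ii + (jj - 1L) * nd[1] + (kk - 1L) * nd[1] * nd[2]
  En <- matrix(0L, ne, 8)
  for (c8 in 1:8) {
    En[, c8] <- node_of(es[, 1] + corner[c8, 1], es[, 2] + corner[c8, 2],
                        es[, 3] + corner[c8, 3])
  }
  active_nodes <- sort(unique(as.vector(En)))
  node_map <- integer(prod(nd))
  node_map[active_nodes] <- seq_along(active_nodes)
  nn <- length(active_nodes)
  ndof <- 3L * nn
  # element dof matrix (ne x 24), interleaved (x, y, z per node)
  Edof <- matrix(0L, ne, 24)
  for (c8 in 1:8) {
    base <- 3L * (node_map[En[, c8]] - 1L)
    Edof[, 3 * c8 - 2] <- base + 1L
    Edof[, 3 * c8 - 1] <- base + 2L
    Edof[, 3 * c8] <- base + 3L
  }
  K <- NULL
  for (s0 in seq(1L, ne, by = chunk)) {
    rows <- s0:min(s0 + chunk - 1L, ne)
    nb <- length(rows)
    ii <- rep(t(Edof[rows, , drop = FALSE]), times = 24)
    dim(ii) <- NULL
    jj <- rep(Edof[rows, , drop = FALSE], each = 24)
    dim(jj) <- NULL
    # layout of (ii, jj): dof index a fastest, element e next, dof index b
    # slowest; Ke[a, b] couples row dof a with column dof b
    xx <- as.vector(vapply(1:24, function(b) rep(Ke[, b], nb), numeric(24 * nb)))
    Kb <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
    K <- if (is.null(K)) Kb else K + Kb
  }
  # component id per active node (from the elements; shared nodes keep the
  # last writer, which is immaterial for pinning)
  ecomp <- attr(solid, "element_comp")
  node_comp <- integer(nn)
  if (!is.null(ecomp)) {
    for (c8 in 1:8) node_comp[node_map[En[, c8]]] <- ecomp
  }
  list(K = K, node_map = node_map, active_nodes = active_nodes,
       nd = nd, ndof = ndof, node_comp = node_comp)
}

#' Directional effective moduli of a binary microstructure
#'
#' Computes the effective Young's modulus along each requested axis by
#' linear voxel homogenization: solid voxels become trilinear hexahedral
#' elements with modulus `solid_modulus` and Poisson ratio `poisson`, pore
#' voxels are void. The loaded face receives a uniform axial displacement
#' (rigid frictionless platen), the opposite face is fixed along the load
#' axis only, lateral faces are traction-free, and rigid in-plane motions
#' are pinned. The effective modulus is `E = F l / (u A)` with `F` the
#' total axial reaction on the loaded face and `A` the full cross-section
#' (pores included).
#'
#' @param binary a [binary_microstructure()].
#' @param solid_modulus_MPa Young's modulus of the solid phase, MPa.
#' @param poisson Poisson ratio in (0, 0.5); default 0.49
#'   (near-incompressible soft tissue).
#' @param axes axes to load (default all three).
#' @return A list of class `homogenization_result`: `E_MPa` (named vector),
#'   `solid_modulus_MPa`, `poisson`, `anisotropy_ratio`
#'   (`E_z / mean(E_x, E_y)` when all three axes are computed), `dim`,
#'   `voxel_size_um`.
#' @export
homogenize_effective_moduli <- function(binary, solid_modulus_MPa, poisson = 0.49,
                                        axes = c("x", "y", "z")) {
  stopifnot(inherits(binary, "binary_microstructure"))
  stopifnot(solid_modulus_MPa > 0, poisson > 0, poisson < 0.5)
  solid <- solid_mask(binary)
  h <- voxel_size(binary)
  d <- dim(solid)
  comp <- mask_components6(solid)
  E_out <- stats::setNames(rep(NA_real_, length(axes)), axes)
  for (ax in axes) {
    ai <- axis_index(ax)
    # only components spanning from the fixed to the loaded face carry load
    inlet_c <- unique(as.vector(index_dim(comp, ai, 1L)))
    outlet_c <- unique(as.vector(index_dim(comp, ai, d[ai])))
    keep <- setdiff(intersect(inlet_c, outlet_c), 0L)
    if (!length(keep)) {
      E_out[ax] <- 0
      next
    }
    use <- array(solid & (comp %in% keep), d)
    attr(use, "element_comp") <- comp[use]
    asm <- assemble_voxel_stiffness(use, h, solid_modulus_MPa, poisson)
    E_out[ax] <- homogenize_one_axis(asm, d, h, ai)
  }
  aniso <- if (all(c("x", "y", "z") %in% axes) && mean(E_out[c("x", "y")]) > 0) {
    unname(E_out["z"] / mean(E_out[c("x", "y")]))
  } else NA_real_
  structure(list(
    E_MPa = E_out, solid_modulus_MPa = solid_modulus_MPa, poisson = poisson,
    anisotropy_ratio = aniso, dim = d, voxel_size_um = h
  ), class = "homogenization_result")
}

homogenize_one_axis <- function(asm, d, h, ai) {
  nd <- asm$nd
  nn <- length(asm$active_nodes)
  coords <- arrayInd(asm$active_nodes, nd)   # node grid coordinates (1-based)
  l_ax <- d[ai] * h
  u_hat <- 1e-3 * l_ax
  tr <- setdiff(1:3, ai)
  A_cross <- prod(d[tr]) * h^2

  fixed_face <- coords[, ai] == 1L
  loaded_face <- coords[, ai] == nd[ai]

  known <- logical(asm$ndof)
  uval <- numeric(asm$ndof)
  dof <- function(node_rows, comp) 3L * (which(node_rows) - 1L) + comp
  known[dof(fixed_face, ai)] <- TRUE
  known[dof(loaded_face, ai)] <- TRUE
  uval[dof(loaded_face, ai)] <- u_hat
  # pin rigid in-plane motions on the fixed face, per solid component
  for (cc in setdiff(unique(asm$node_comp), 0L)) {
    ff <- which(fixed_face & asm$node_comp == cc)
    if (!length(ff)) next
    p0 <- ff[1]
    known[3L * (p0 - 1L) + tr] <- TRUE
    d1 <- coords[ff, tr[1]] - coords[p0, tr[1]]
    d2 <- coords[ff, tr[2]] - coords[p0, tr[2]]
    rr <- d1^2 + d2^2
    if (any(rr > 0)) {
      p1i <- which.max(rr)
      p1 <- ff[p1i]
      # block rotation about the load axis: constrain the in-plane dof
      # most nearly perpendicular to the lever arm
      if (abs(d1[p1i]) >= abs(d2[p1i])) {
        known[3L * (p1 - 1L) + tr[2]] <- TRUE
      } else {
        known[3L * (p1 - 1L) + tr[1]] <- TRUE
      }
    }
  }

  K <- asm$K
  free <- which(!known)
  kn <- which(known)
  rhs <- -K[free, kn, drop = FALSE] %*% uval[kn]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(K[free, free, drop = FALSE]),
                         LDL = FALSE, super = TRUE)
  uf <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  u <- uval
  u[free] <- uf
  r <- as.numeric(K %*% u)
  F_total <- sum(r[dof(loaded_face, ai)])
  unname(F_total * l_ax / (u_hat * A_cross))
}

#' @export
print.homogenization_result <- function(x, ...) {
  cat("<homogenization_result>\n")
  for (ax in names(x$E_MPa)) {
    cat(sprintf("  E_%s = %.4g MPa\n", ax, x$E_MPa[ax]))
  }
  cat(sprintf("  solid modulus %.4g MPa, poisson %.3f", x$solid_modulus_MPa, x$poisson))
  if (!is.na(x$anisotropy_ratio)) cat(sprintf(", anisotropy E_z/mean(E_x,E_y) = %.3f",
                                              x$anisotropy_ratio))
  cat("\n")
  invisible(x)
}

#' Calibrate the solid-phase modulus to a target effective modulus
#'
#' Exploits the linearity of the homogenization in the solid modulus: one
#' solve at unit modulus gives `E_unit`, so the solid modulus matching the
#' target effective modulus along `axis` is `target / E_unit`. A confirming
#' solve at the returned modulus is performed and must agree with the
#' target within `check_tol`.
#'
#' @param binary a [binary_microstructure()].
#' @param target_E_MPa target effective modulus along `axis`, MPa.
#' @param axis load axis.
#' @param poisson Poisson ratio.
#' @param check_tol relative tolerance of the confirming solve (default 0.01).
#' @return The solid modulus (MPa), with attribute `confirmed_E_MPa`.
#' @export
calibrate_solid_modulus <- function(binary, target_E_MPa, axis = "z", poisson = 0.49,
                                    check_tol = 0.01) {
  stopifnot(target_E_MPa > 0)
  E_unit <- homogenize_effective_moduli(binary, 1, poisson, axes = axis)$E_MPa[[1]]
  if (E_unit <= 0) stop("solid phase does not percolate along the load axis", call. = FALSE)
  sm <- target_E_MPa / E_unit
  confirm <- homogenize_effective_moduli(binary, sm, poisson, axes = axis)$E_MPa[[1]]
  if (abs(confirm - target_E_MPa) > check_tol * target_E_MPa) {
    warning(sprintf("confirming solve gave %.4g MPa vs target %.4g MPa", confirm,
                    target_E_MPa), call. = FALSE)
  }
  structure(sm, confirmed_E_MPa = confirm)
}
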