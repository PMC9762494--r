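#' Specification objects for synthetic inputs
#'
#' Constructors for the parameter bundles consumed by the generators. Each
#' generator is a pure function of its spec, including the seed: the same
#' spec always yields bitwise-identical output, and no global RNG state
#' leaks.
#'
#' `phantom_spec()` describes an anisotropic porous volume built from
#' near-axial "chambered" channels: aligned wavy tubes whose radius is
#' modulated along the alignment axis so that the pore space consists of
#' bead-like chambers separated by constrictions, emulating the axon
#' channels of the endoneurium extracellular matrix. Defaults target the
#' microstructure of human nerve endoneurium: porosity 35.5%, pore
#' (chamber) size 11.8 um.
#'
#' @param shape integer triple, voxels per axis (each >= 16).
#' @param voxel_size_um voxel edge, micrometres.
#' @param target_porosity pore-phase volume fraction in (0, 1).
#' @param tube_radius_mean_um,tube_radius_sd_um channel radius distribution
#'   (mean must exceed the voxel size).
#' @param alignment_axis `"x"`, `"y"` or `"z"` — the channel direction.
#' @param waviness dimensionless >= 0: transverse centreline perturbation
#'   amplitude as a fraction of the axial length.
#' @param chamber_esd_um target equivalent spherical diameter of one pore
#'   chamber; sets the axial modulation period `l = esd^3 / (6 r_mean^2)`.
#' @param modulation_amplitude relative amplitude of the radius modulation
#'   creating the chamber constrictions (0 disables chambering).
#' @param seed integer RNG seed.
#' @return A list with class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 96),
                         voxel_size_um = 1.2,
                         target_porosity = 0.355,
                         tube_radius_mean_um = 4.2,
                         tube_radius_sd_um = 0.8,
                         alignment_axis = "z",
                         waviness = 0.04,
                         chamber_esd_um = 11.8,
                         modulation_amplitude = 0.45,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 16))
  if (!(target_porosity > 0 && target_porosity < 1)) {
    stop("`target_porosity` must lie in (0, 1)", call. = FALSE)
  }
  if (tube_radius_mean_um <= voxel_size_um) {
    stop("`tube_radius_mean_um` must exceed the voxel size", call. = FALSE)
  }
  stopifnot(waviness >= 0, modulation_amplitude >= 0, modulation_amplitude < 1)
  structure(list(
    shape = shape, voxel_size_um = voxel_size_um,
    target_porosity = target_porosity,
    tube_radius_mean_um = tube_radius_mean_um,
    tube_radius_sd_um = tube_radius_sd_um,
    alignment_axis = alignment_axis, waviness = waviness,
    chamber_esd_um = chamber_esd_um,
    modulation_amplitude = modulation_amplitude,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param blur_sigma Gaussian blur, voxels.
#' @param noise_sd additive Gaussian noise, grayscale units.
#' @param fg_level,bg_level grayscale means of the solid and pore phases
#'   (must differ; 8-bit range 0-255).
#' @export
noise_spec <- function(blur_sigma = 1, noise_sd = 10,
                       fg_level = 200, bg_level = 50, seed = 1L) {
  if (fg_level == bg_level) stop("`fg_level` must differ from `bg_level`", call. = FALSE)
  stopifnot(noise_sd >= 0, blur_sigma >= 0)
  structure(list(
    blur_sigma = blur_sigma, noise_sd = noise_sd,
    fg_level = fg_level, bg_level = bg_level, seed = as.integer(seed)
  ), class = "noise_spec")
}

#' @rdname phantom_spec
#' @param model_name one of `"yeoh3"`, `"mooney_rivlin"`, `"ogden1"`,
#'   `"neo_hookean"`; ignored when `linear_modulus_MPa` is given (piecewise
#'   J-curve mode).
#' @param params named list of model coefficients, MPa (see
#'   [uniaxial_stress()]).
#' @param toe_strain engineering strain at which the toe region ends
#'   (piecewise J-curve mode).
#' @param linear_modulus_MPa post-toe slope, MPa; supplying it selects the
#'   piecewise J-curve mode.
#' @param max_strain largest engineering strain sampled.
#' @param n_points number of samples (>= 10).
#' @param noise_rel_sd additive noise SD as a fraction of the peak stress.
#' @export
curve_spec <- function(model_name = "yeoh3",
                       params = list(C10 = 1, C20 = 0, C30 = 0),
                       toe_strain = 0.13,
                       linear_modulus_MPa = NULL,
                       max_strain = 0.4,
                       n_points = 100L,
                       noise_rel_sd = 0,
                       seed = 1L) {
  stopifnot(n_points >= 10, max_strain > 0, noise_rel_sd >= 0)
  if (!is.null(linear_modulus_MPa) && !(toe_strain > 0 && toe_strain < max_strain)) {
    stop("`toe_strain` must lie in (0, max_strain)", call. = FALSE)
  }
  structure(list(
    model_name = model_name, params = params, toe_strain = toe_strain,
    linear_modulus_MPa = linear_modulus_MPa, max_strain = max_strain,
    n_points = as.integer(n_points), noise_rel_sd = noise_rel_sd,
    seed = as.integer(seed)
  ), class = "curve_spec")
}

# Evaluate an expression under a private RNG stream, restoring global state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Analytic channel and plate phantoms
#'
#' Deterministic fixtures with closed-form porosity and permeability.
#' `generate_channel_phantom()` carves a single straight circular channel of
#' pore phase along `axis` through an otherwise solid block;
#' `generate_plate_phantom()` carves one planar pore slab of thickness `gap`
#' normal to `normal_axis`. A voxel belongs to the pore if its centre lies
#' inside the analytic shape.
#'
#' @param shape integer triple, voxels per axis.
#' @param voxel_size_um voxel edge, micrometres.
#' @param radius_um channel radius; `2 * radius_um` must fit in both
#'   transverse extents.
#' @param axis channel direction (`"x"`, `"y"`, `"z"`).
#' @return A [binary_microstructure()].
#' @examples
#' ch <- generate_channel_phantom(c(64, 64, 64), 1, radius_um = 16, axis = "z")
#' compute_porosity(ch) # ~ pi * 16^2 / 64^2
#' @export
generate_channel_phantom <- function(shape, voxel_size_um, radius_um, axis = "z") {
  shape <- as.integer(shape)
  ai <- axis_index(axis)
  tr <- setdiff(1:3, ai)
  ext <- shape[tr] * voxel_size_um
  if (any(2 * radius_um >= ext)) {
    stop("channel diameter does not fit in the transverse extents", call. = FALSE)
  }
  c1 <- voxel_centers(shape[tr[1]], voxel_size_um) - ext[1] / 2
  c2 <- voxel_centers(shape[tr[2]], voxel_size_um) - ext[2] / 2
  disc <- outer(c1^2, c2^2, `+`) <= radius_um^2   # pore in the transverse plane
  solid_tr <- !disc
  # replicate the transverse pattern along the channel axis
  perm <- c(tr, ai)
  rep_arr <- array(rep(solid_tr, shape[ai]), c(shape[tr], shape[ai]))
  solid <- aperm(rep_arr, order(perm))
  binary_microstructure(solid, voxel_size_um)
}

#' @rdname generate_channel_phantom
#' @param gap_um slab thickness (>= 1 voxel, <= extent along `normal_axis`).
#' @param normal_axis axis normal to the pore slab.
#' @export
generate_plate_phantom <- function(shape, voxel_size_um, gap_um, normal_axis = "z") {
  shape <- as.integer(shape)
  ai <- axis_index(normal_axis)
  ext <- shape[ai] * voxel_size_um
  if (gap_um < voxel_size_um) stop("`gap_um` must be at least one voxel", call. = FALSE)
  if (gap_um > ext) stop("`gap_um` exceeds the domain extent", call. = FALSE)
  cen <- voxel_centers(shape[ai], voxel_size_um)
  lo <- (ext - gap_um) / 2
  in_slab <- cen >= lo & cen < lo + gap_um
  solid <- array(TRUE, shape)
  solid <- assign_dim(solid, ai, which(in_slab), FALSE)
  binary_microstructure(solid, voxel_size_um)
}

#' Generate an aligned chambered-channel phantom
#'
#' Builds the pore phase as a union of near-axial wavy tubes with modulated
#' radius (see [phantom_spec()]). Tube centrelines are placed by
#' Poisson-disc-like rejection sampling in the transverse plane; a global
#' radius scale factor is then tuned by bisection (at most 30 iterations)
#' until the achieved porosity is within 0.02 of `target_porosity`.
#'
#' @param spec a [phantom_spec()].
#' @return A [binary_microstructure()] with attributes
#'   `achieved_porosity`, `porosity_converged`, `radius_scale`, `n_tubes`.
#' @export
generate_fiber_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    ai <- axis_index(spec$alignment_axis)
    tr <- setdiff(1:3, ai)
    h <- spec$voxel_size_um
    n_ax <- spec$shape[ai]
    n1 <- spec$shape[tr[1]]
    n2 <- spec$shape[tr[2]]
    L_ax <- n_ax * h
    ext1 <- n1 * h
    ext2 <- n2 * h
    rbar <- spec$tube_radius_mean_um
    amp <- spec$modulation_amplitude
    wav_amp <- spec$waviness * L_ax

    # number of tubes aimed so that the bisection scale lands near 1
    n_target <- max(3L, round(spec$target_porosity * ext1 * ext2 /
                                (pi * rbar^2 * (1 + amp^2 / 2)) * 1.05))

    # Poisson-disc-like rejection sampling of centres, inset so that wavy
    # centrelines stay inside the domain. Each candidate carries its own
    # radius and must clear every accepted tube by a radius-aware margin,
    # so wide channels do not coalesce with their neighbours.
    margin <- wav_amp + 0.5 * rbar
    margin <- min(margin, 0.4 * min(ext1, ext2))
    centers <- matrix(numeric(0), ncol = 2)
    radii <- numeric(0)
    attempts <- 0L
    while (nrow(centers) < n_target && attempts < 400L * n_target) {
      attempts <- attempts + 1L
      p <- c(runif(1, margin, ext1 - margin), runif(1, margin, ext2 - margin))
      r_p <- max(1.2 * h, stats::rnorm(1, rbar, spec$tube_radius_sd_um))
      if (nrow(centers) == 0 ||
          all((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 >=
                (1.05 * (radii + r_p))^2)) {
        centers <- rbind(centers, p)
        radii <- c(radii, r_p)
      }
    }
    nt <- nrow(centers)
    # axial radius-modulation period from the chamber ESD target; the
    # (1 + a^2/2) factor is the mean cross-section inflation of the
    # sinusoidal radius modulation
    period <- spec$chamber_esd_um^3 / (6 * rbar^2 * (1 + amp^2 / 2))
    phase_mod <- runif(nt, 0, 2 * pi)
    # coherent undulation (fascicle-level crimp): all channels share the
    # same centreline waves, so neighbouring channels never collide
    phase_wx <- rep(runif(1, 0, 2 * pi), nt)
    phase_wy <- rep(runif(1, 0, 2 * pi), nt)

    zc <- voxel_centers(n_ax, h)
    x1 <- voxel_centers(n1, h)
    x2 <- voxel_centers(n2, h)

    # normalized squared distance field: rho(v) = min over tubes of
    # d^2(v, centreline) / r_tube(z)^2; pore at scale s <=> rho <= s^2
    rho <- array(Inf, c(n1, n2, n_ax))
    for (t in seq_len(nt)) {
      cx <- centers[t, 1] + wav_amp * sin(2 * pi * zc / L_ax + phase_wx[t])
      cy <- centers[t, 2] + wav_amp * sin(2 * pi * zc / L_ax + phase_wy[t])
      rz <- radii[t] * (1 + amp * sin(2 * pi * zc / period + phase_mod[t]))
      rz2 <- rz^2
      for (k in seq_len(n_ax)) {
        d2 <- outer((x1 - cx[k])^2, (x2 - cy[k])^2, `+`) / rz2[k]
        rho[, , k] <- pmin(rho[, , k], d2)
      }
    }

    # bisection on the global radius scale factor; the stop tolerance is
    # well inside the +/- 0.02 contract so seed-to-seed variation keeps a
    # comfortable margin
    target <- spec$target_porosity
    por <- function(s) mean(rho <= s^2)
    lo <- 0.25; hi <- 2.5
    s <- 1
    converged <- FALSE
    for (it in seq_len(30L)) {
      s <- (lo + hi) / 2
      p <- por(s)
      if (abs(p - target) <= 0.005) { converged <- TRUE; break }
      if (p < target) lo <- s else hi <- s
    }
    achieved <- por(s)
    if (!converged) converged <- abs(achieved - target) <= 0.02
    if (!converged && abs(achieved - target) > 0.02) {
      warning(sprintf(
        "porosity target %.3f not reached (achieved %.3f)", target, achieved
      ), call. = FALSE)
    }
    pore <- rho <= s^2
    # back to xyz order: current dims are (tr1, tr2, axis)
    perm <- c(tr, ai)
    solid <- aperm(!pore, order(perm))
    out <- binary_microstructure(solid, h)
    attr(out, "achieved_porosity") <- achieved
    attr(out, "porosity_converged") <- converged || abs(achieved - target) <= 0.02
    attr(out, "radius_scale") <- s
    attr(out, "n_tubes") <- nt
    out
  })
}

#' Render a binary volume as a noisy grayscale stack
#'
#' Emulates micro-CT contrast: solid voxels take `fg_level`, pore voxels
#' `bg_level`; the two-level image is Gaussian-blurred (separable kernel,
#' truncated at 3 sigma) and additive Gaussian noise is applied, then values
#' are clipped to the 8-bit range and rounded.
#'
#' @param binary a [binary_microstructure()].
#' @param noise a [noise_spec()].
#' @return A [grayscale_volume()] (integer 0-255).
#' @export
render_grayscale <- function(binary, noise) {
  stopifnot(inherits(binary, "binary_microstructure"), inherits(noise, "noise_spec"))
  if (noise$fg_level < 0 || noise$fg_level > 255 || noise$bg_level < 0 || noise$bg_level > 255) {
    stop("fg/bg levels must lie in the 8-bit range [0, 255]", call. = FALSE)
  }
  v <- array(ifelse(solid_mask(binary), noise$fg_level, noise$bg_level), dim(binary))
  if (noise$blur_sigma > 0) v <- gaussian_blur3(v, noise$blur_sigma)
  with_seed(noise$seed, {
    if (noise$noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise$noise_sd)
  })
  v <- array(as.integer(round(pmin(pmax(v, 0), 255))), dim(binary))
  grayscale_volume(v, voxel_size(binary))
}

# separable Gaussian blur with edge replication
gaussian_blur3 <- function(a, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  for (d in 1:3) {
    out <- array(0, dim(a))
    n <- dim(a)[d]
    for (s in -r:r) {
      shifted <- shift3(a, d, s, fill = NA)
      # replicate edges: fill NA planes with the nearest valid plane
      if (s > 0) {
        edge <- index_dim(a, d, 1L)
        for (j in seq_len(s)) shifted <- assign_dim(shifted, d, j, edge)
      } else if (s < 0) {
        edge <- index_dim(a, d, n)
        for (j in (n + s + 1):n) shifted <- assign_dim(shifted, d, j, edge)
      }
      out <- out + w[s + r + 1] * shifted
    }
    a <- out
  }
  a
}

#' Generate a synthetic uniaxial stress-strain curve
#'
#' Two modes (see [curve_spec()]): a hyperelastic closed-form curve from a
#' named incompressible model, or a piecewise J-curve with a quadratic toe
#' region (zero initial slope, C1-continuous at `toe_strain`) followed by a
#' linear segment whose slope equals `linear_modulus_MPa` exactly before
#' noise.
#'
#' @param spec a [curve_spec()].
#' @return A tibble of class `stress_strain_curve` with columns `stretch`,
#'   `strain`, `stress_MPa`; attribute `clipped_points` counts noisy values
#'   clipped at zero.
#' @export
generate_stress_strain <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  strain <- seq(0, spec$max_strain, length.out = spec$n_points)
  lambda <- 1 + strain
  if (!is.null(spec$linear_modulus_MPa)) {
    E <- spec$linear_modulus_MPa
    et <- spec$toe_strain
    stress <- ifelse(strain <= et,
      E * strain^2 / (2 * et),          # toe: slope 0 at origin, E at toe end
      E * (strain - et / 2)             # linear: slope E, C1 at the junction
    )
  } else {
    stress <- uniaxial_stress(
      hyperelastic_params(spec$model_name, spec$params), lambda
    )
  }
  clipped <- 0L
  if (spec$noise_rel_sd > 0) {
    with_seed(spec$seed, {
      stress <- stress + stats::rnorm(length(stress), 0, spec$noise_rel_sd * max(stress))
    })
    clipped <- sum(stress < 0)
    stress <- pmax(stress, 0)
    stress[1] <- 0   # keep the undeformed point exact
  }
  out <- tibble::tibble(stretch = lambda, strain = strain, stress_MPa = stress)
  class(out) <- c("stress_strain_curve", class(out))
  attr(out, "clipped_points") <- clipped
  out
}

#' Generate a falling-head permeameter record for a known permeability
#'
#' Inverts the falling-head working equations: the hydraulic conductivity is
#' `K = k_true * rho * g / mu` and the elapsed time to fall from head `L1`
#' to `L2` is `t = a * H / (A * K) * log(L1 / L2)`, so that reducing the
#' record recovers `k_true` exactly (round-trip identity).
#'
#' @param k_true intrinsic permeability, m^2.
#' @param a_m2 standpipe cross-section, m^2.
#' @param A_m2 sample cross-section, m^2.
#' @param H_m sample height, m.
#' @param L1_m,L2_m initial and final head, m (`L1 > L2 > 0`).
#' @param fluid a [fluid_properties()].
#' @return A one-row `falling_head_test` tibble (see [falling_head_test()]).
#' @export
generate_falling_head_record <- function(k_true, a_m2, A_m2, H_m, L1_m, L2_m,
                                         fluid = fluid_properties()) {
  if (!(L1_m >= L2_m && L2_m > 0)) stop("need L1 >= L2 > 0", call. = FALSE)
  if (any(c(k_true, a_m2, A_m2, H_m) <= 0)) {
    stop("permeability and geometry must be positive", call. = FALSE)
  }
  K <- k_true * fluid$density * fluid$gravity / fluid$viscosity
  t <- a_m2 * H_m / (A_m2 * K) * log(L1_m / L2_m)
  falling_head_test(
    a_m2 = a_m2, A_m2 = A_m2, H_m = H_m,
    L1_m = L1_m, L2_m = L2_m, t_s = t
  )
}
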