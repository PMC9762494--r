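---
title: "Characterizing porous soft-tissue microstructure: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing porous soft-tissue microstructure: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and scientific setting

The endoneurium extracellular matrix (eECM) of a peripheral-nerve fascicle
is an anisotropic porous solid: a honeycomb of collagenous walls enclosing
near-axial channels that once housed axons. Its transport and mechanical
properties — porosity, pore size, tortuosity, surface area-to-volume ratio
(SAVR), permeability and directional stiffness — are the design targets for
biomimetic nerve-guidance scaffolds. `poromech` implements the full
characterization chain for such microstructures from 3D grayscale image
stacks (e.g. micro-CT at a few micrometres per voxel): threshold
calibration and segmentation, representative-volume-element (RVE)
selection, voxel morphometrics, image-based permeability via Stokes flow
and Darcy's law, falling-head permeameter reduction, and directional
effective stiffness with hyperelastic constitutive fitting.

Because raw scans of this tissue are generally not redistributable, the
package ships a synthetic-data module whose phantoms have known ground
truth; every downstream stage is validated against analytic closed forms
or the generator's truth, never against itself.

## Segmentation

Grayscale stacks are smoothed with a cubic **mean filter** whose window is
clipped at the volume boundary — no padding values are invented, so edge
slices are not biased toward an arbitrary fill level. Binarization labels
voxels **strictly above** the threshold as solid (tissue) and the rest as
pore; the threshold is carried in the result's provenance.

Two threshold selectors are provided:

* `histogram_minimum_threshold()` takes the grayscale at the minimum of the
  (moving-average smoothed, width 5 bins) histogram between its two highest
  *distinct* modes, ties resolved toward the lower bin. A candidate second
  mode must be separated from the first by a genuine valley — the smoothed
  count must dip below 80% of the candidate's height — because on heavily
  overlapping mixtures a shoulder bump of the main mode can otherwise
  masquerade as a second mode.
* `calibrate_threshold_to_area_rate()` reproduces the histology-matched
  calibration used for tissue whose dynamic range is arbitrary: for every
  candidate threshold the mean per-slice solid-pixel fraction ("surface
  area rate") is computed, and the threshold minimizing the absolute
  deviation from the histological section's solid-area fraction is chosen.
  The full rate-vs-threshold table is returned for plotting. The "surface
  area rate" is interpreted as a per-slice 2D fraction (the histological
  comparison is per-section); a 3D surface measure would be a different
  quantity.

`assess_rve_convergence()` samples random sub-cubes per candidate edge and
recommends the smallest edge whose porosity SD is at most 0.01 and whose
mean porosity lies within 0.01 of the largest edge's mean. These two
tolerances are this package's own (configurable) criterion; no standard
value exists.

## Morphometry

* **Porosity** is the pore-voxel fraction.
* **SAVR** is the internal solid-pore interface area over total volume,
  with the domain's outer boundary faces excluded so the measure does not
  depend on where the ROI was cut. The primary estimator triangulates the
  0.5 level set of the mean-filtered (half-width 1) solid indicator by
  *marching tetrahedra* — six tetrahedra per cell sharing the main
  diagonal, each contributing a triangle or a planar quad, no case tables —
  which converges to the true area of smooth interfaces (a 10 um sphere is
  recovered within ~1%). A voxel-face-counting estimator is reported
  alongside as an upper-bias oracle; for smooth surfaces it overestimates
  by up to ~1.5x (exactly 1.5x for a sphere in the continuum limit).
* **Tortuosity** is geodesic: for each phase voxel on the inlet face the
  shortest within-phase path to the opposite face is computed by Dijkstra
  on the 26-connected voxel graph with Euclidean edge weights, and divided
  by the centre-to-centre domain extent. The summary is the **mean over
  inlet voxels** of the percolating component (an aggregate is less
  noise-dominated than the single global minimum, which is also reported).
  26-connectivity is used because 6-connectivity exaggerates oblique path
  lengths (a diagonal detour costs `2` instead of `sqrt(2)` per step).
* **Pore size and wall thickness** come from watershed object separation
  on the Euclidean distance transform (EDT) of each phase, followed by the
  equivalent spherical diameter `ESD = (6 V / pi)^(1/3)` per object. The
  EDT is an exact 3D transform (separable lower-envelope scan). The
  watershed is marker-based: markers are the *h-maxima* of the EDT —
  regional maxima surviving morphological reconstruction of `EDT - h`
  under the EDT, with plateau-aware maximum detection — so maxima whose
  prominence above the connecting saddle is below `h` (default 2 voxels)
  never seed spurious splits; labels then flood downhill level by level.
  All stages are deterministic.

## Image-based permeability

Creeping (Stokes) flow is solved on the pore space with a staggered
**marker-and-cell (MAC)** finite-volume scheme: velocity components on
cell faces, pressures at cell centres, exact per-cell mass conservation.
No-slip is imposed on all solid interfaces; tangential wall conditions at
solid faces and at the lateral domain walls act at the physical half-cell
distance through ghost reflection. Steady Stokes rather than full
Navier-Stokes is appropriate because permeability is defined in the
Darcy regime (`Re < 1`), where inertial terms are negligible; the computed
Reynolds number (`Re = rho v d / mu` with `v = Q / (phi A)` and `d` the
mean pore ESD by default) is attached to every permeability result as a
validity flag.

Flow at rate `Q` along an axis can be driven two ways:

* `inlet = "pressure"` (default): the first and last pore layers act as
  uniform-pressure reservoirs; the linear solution is rescaled to carry
  exactly `Q`. By Stokes linearity this equals prescribing the *developed*
  inflow profile at rate `Q`. It reproduces Hagen-Poiseuille pipe flow at
  64^3 within ~1%.
* `inlet = "uniform"`: a flat profile carrying `Q` on the inlet pore
  faces. A flat profile must develop over roughly one channel width,
  and the associated excess entrance pressure drop biases the apparent
  permeability low (about -18% on the 64^3 pipe fixture). The mode is kept
  for comparison, but the reservoir inlet is the default because the
  closed-form verification shows it is the faithful way to realize
  "constant flow rate in, zero static pressure out" on short domains.

Lateral boundaries are no-slip walls by default (the enclosed-RVE setup);
`lateral = "slip"` provides symmetry planes for verifying against closed
forms of laterally unbounded geometries (an infinite slit). With no-slip
walls the slit fixture correctly reproduces the *rectangular duct* value
(about 16% below the infinite-slit form at aspect 4 — the Cornish
correction), which is physics, not error.

The discrete saddle-point system is reduced to the pressure Schur
complement, solved by conjugate gradients; the three velocity Laplacian
blocks are factorized once with supernodal sparse Cholesky (CHOLMOD), so
momentum is satisfied to machine precision and the divergence residual
equals the CG tolerance (default 1e-10 relative). Pore regions not
connected to the inlet or outlet are excluded from the fluid domain (they
carry no flow and would make the pressure system singular).

Darcy reduction uses `k = mu L Q / (A dP)` with `dP` the difference of
pore-area-weighted mean pressures between the first and last cell layers
and `L` their separation `(n - 1) h`, which is the consistent pairing for
a uniform gradient sampled at cell centres. The falling-head reduction
implements `K = a H / (A t) ln(L1 / L2)` and `k = K mu / (rho g)`;
replicate permeabilities are aggregated as mean and population
(divide-by-n) SD.

## Mechanics

`linear_region_modulus()` reduces a J-shaped uniaxial curve to its post-toe
linear modulus and toe strain. The linear window is the widest sliding
window (at least 30% of the points) whose linear-fit RMSE stays within 1.5x
the curve's noise floor, estimated robustly from second differences (which
are blind to any linear trend). A plain R^2 threshold cannot do this job:
a straight line through an entire J-curve with a 13% toe already reaches
R^2 = 0.99, so an R^2-based detector swallows the toe. The residual
criterion recovers the toe strain exactly on noiseless curves; at 1%
noise the toe estimate biases low (windows creep into the toe while the
systematic deviation hides below the noise) while the slope stays within
~3%.

Constitutive fitting uses the incompressible uniaxial closed forms of
four families (nominal stress; `I1 = lambda^2 + 2/lambda`):
Yeoh 3rd order, Mooney-Rivlin, one-term Ogden and neo-Hookean. Yeoh,
Mooney-Rivlin and neo-Hookean stresses are linear in their coefficients
and are fitted by ordinary least squares (exact recovery on noiseless
data); Ogden by Levenberg-Marquardt started from the small-strain slope.
Each fit carries a stability flag (tangent modulus positive over the data
range). `select_best_model()` ranks stable fits by MSE with a 10% tie
tolerance favouring fewer coefficients, so a richer nested model never
wins on a statistically meaningless margin; Marlow-type non-parametric
models are out of scope (they interpolate the test curve rather than
yield coefficients).

Directional stiffness comes from linear voxel homogenization: solid voxels
become trilinear hexahedral elements (2x2x2 Gauss), pores are void. The
loaded face receives a uniform axial displacement (rigid frictionless
platen), the opposite face is fixed axially, lateral faces are
traction-free, and in-plane rigid motions are pinned per connected solid
component (components not spanning both faces carry no load and are
dropped). The effective modulus is `E = F l / (u A)` with `A` the full
cross-section. A linear solve is the appropriate surrogate because the
target quantity is the modulus of the *linear phase* of the J-curve; the
large-deformation regime is out of scope. `calibrate_solid_modulus()`
exploits linearity — one unit-modulus solve, then scaling — to find the
solid-phase modulus whose RVE response matches a target effective modulus
(e.g. the measured 38.5 MPa linear modulus), with a confirming solve.

The Poisson ratio defaults to 0.49 (near-incompressible hydrated soft
tissue); it is configurable and the homogenization is insensitive to it at
the reported precision for the geometries studied.

## The synthetic-data module

`generate_channel_phantom()` and `generate_plate_phantom()` are analytic
fixtures (cylindrical channel, planar slit) whose porosity and
permeability have closed forms; a voxel belongs to the pore if its centre
lies inside the analytic shape, matching the counting oracle.

`generate_fiber_phantom()` emulates the eECM: the pore space is a union of
near-axial channels placed by radius-aware Poisson-disc rejection sampling
in the transverse plane (each candidate must clear every accepted tube by
1.05x the sum of radii, so wide channels do not coalesce). Channels
undulate coherently — all share the same centreline wave (fascicle-level
crimp), which keeps neighbours from colliding — and their radius is
modulated axially so the pore space consists of bead-like chambers
separated by constrictions, emulating the septated axon channels whose
watershed separation defines the "pore size". Defaults target the
published endoneurium microstructure: porosity 35.5%, chamber ESD 11.8 um
(the modulation period is derived from that target:
`l = esd^3 / (6 r^2 (1 + a^2/2))`), channel radius 4.2 +/- 0.8 um,
voxel 1.2 um at 96^3 (a ~115 um cube), waviness 0.04, modulation
amplitude 0.45. The amplitude and voxel size are chosen together so that
chamber necks exceed the watershed's default prominence threshold
(h = 2 voxels). A global radius scale is tuned by bisection (at most 30
iterations) until porosity is within 0.005 of target — comfortably inside
the +/-0.02 contract, so seed-to-seed variation keeps margin.

What the phantom does *not* emulate: iodine-staining contrast physics,
beam hardening or reconstruction artifacts; wall-thickness statistics
beyond what the porosity and channel geometry imply; biological
variability of channel cross-sections (circular cross-sections with
sinusoidal modulation are a stylization). Passing tests on phantoms
therefore validate the *measurement chain*, not the realism of any
particular tissue; measured watershed pore size on the phantom runs
~15-20% above the chamber design ESD because a minority of shallow necks
(below the h-maxima prominence) merge adjacent chambers.

`render_grayscale()` produces noisy 8-bit renderings (two-level image,
separable Gaussian blur, additive Gaussian noise) for threshold
calibration tests, and `generate_stress_strain()` produces either
closed-form hyperelastic curves or piecewise J-curves (quadratic toe with
zero initial slope, C1-continuous junction, exact post-toe slope).
`generate_falling_head_record()` inverts the falling-head equations so
the reduction round-trips to the generating permeability at 1e-3
relative. Every generator is a pure function of its spec including the
seed; no global RNG state leaks.

## Numerical choices and degenerate inputs

* Stokes: CG tolerance 1e-10 (divergence residual), momentum residual at
  machine precision by construction; non-percolating pore space is an
  error; isolated pore pockets are excluded from the fluid domain.
* Homogenization: supernodal Cholesky of the reduced stiffness; pinned
  dofs carry zero load (frictionless platens), so the pin choice does not
  affect the modulus; non-percolating solid gives `E = 0` for that axis.
* Watershed: level step 0.25 voxels in the downhill flood; ties toward
  the larger marker id (deterministic).
* Histogram threshold: unimodal histograms are an error directing the
  user to a manual threshold, never a silent guess.
* Mean filter and EDT treat boundaries by clipping; no reflected or
  zero-padded ghost values anywhere in the measurement chain.
* All randomness flows from explicit seeds through private RNG streams
  that restore global state.

## Problem sizes

The validation suite and the acceptance script use 64^3 domains for the
closed-form flow fixtures (~1% discretization error), 96^3 for the
phantom characterization, and 32^3 RVEs for the directional stiffness
solves (the direct sparse factorization of 3D elasticity grows steeply
with edge length; at 32^3 the three axis solves complete in about two
minutes while reproducing the homogeneous-cube and laminate references to
better than 1% and 3%). These sizes are the package's validation choices;
all solvers accept larger volumes.

## Known limitations

* The geodesic tortuosity definition (mean over inlet voxels of
  26-connected shortest paths) is declared, not claimed identical to
  proprietary "centerline" or "shortest route" implementations in
  commercial packages; values on the same volume may differ by the
  aggregation rule.
* Voxel staircase boundaries bias fine-channel permeability; fixtures at
  r >= 8 voxels keep the bias within a few percent.
* The homogenization is linear-elastic small-strain; it characterizes the
  linear phase of the J-curve only.
* The falling-head reduction assumes a constant-geometry rigid sample;
  swelling or compaction during the test is not modelled.
* Watershed pore sizing undersplits chambers whose neck prominence falls
  below `h`; decreasing `h` below 2 voxels trades that for voxelization
  oversplitting.
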