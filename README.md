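# poromech

Microstructure, permeability and stiffness of porous soft-tissue scaffolds
from 3D voxel images.

## What it is for

The endoneurium extracellular matrix (eECM) of peripheral nerve — like many
soft porous tissues — is an anisotropic honeycomb of collagenous walls
around near-axial channels. Scaffold designers who want to mimic it need a
reproducible pipeline from a 3D grayscale stack (micro-CT, ~3 µm voxels) to
the quantities that drive regeneration: porosity φ, pore size, per-axis
tortuosity τ, surface area-to-volume ratio (SAVR), intrinsic permeability
k, and directional effective stiffness E. `poromech` implements that
pipeline in R, for image analysts and tissue-engineering researchers:

* **Segmentation** — mean-filter smoothing, strictly-greater thresholding,
  histogram-minimum and histology-calibrated threshold selection, cubic ROI
  cropping, RVE-size selection by porosity convergence.
* **Morphometry** — porosity; geodesic tortuosity (26-connected Dijkstra,
  mean over inlet voxels: τ = ⟨L_path⟩ / L_straight ≥ 1); SAVR by marching
  tetrahedra (face-counting oracle reported alongside); watershed pore /
  wall sizing via the equivalent spherical diameter ESD = (6V/π)^(1/3),
  using an exact 3D distance transform and h-maxima markers.
* **Permeability** — staggered-grid (MAC) Stokes flow on the pore space
  with no-slip walls, reduced by Darcy's law k = μLQ/(AΔP), with the
  Reynolds-number validity flag (Re < 1); and the falling-head permeameter
  reduction K = aH/(At)·ln(L1/L2), k = Kμ/(ρg).
* **Mechanics** — toe-region / linear-modulus analysis of J-shaped tensile
  curves; incompressible hyperelastic fitting (Yeoh 3rd order,
  Mooney–Rivlin, one-term Ogden, neo-Hookean) with stability-aware model
  selection; linear voxel homogenization for directional E = F·l/(u·A) and
  solid-modulus calibration to a measured tissue modulus.
* **Synthetic data** — channel/slit fixtures with closed-form answers and
  an endoneurium-like chambered-channel phantom with known ground truth
  (porosity target 35.5%, chamber ESD target 11.8 µm), so the whole chain
  is testable without redistributing scans.

Everything is tidyverse-shaped where data are tabular: curves, permeameter
records, calibration tables and reports are tibbles; results have
`tidy()` / `glance()` / `autoplot()` methods. Volumes are plain 3D arrays
with a voxel-size attribute.

## Worked example

Falling-head permeameter reduction of the bundled worked-example records
(decellularized human nerve fascicles, three samples × three trials):

```r
library(poromech)

reference_falling_head("triplicate") |>
  falling_head_conductivity() |>
  conductivity_to_permeability() |>
  dplyr::select(sample, trial, t_s, K_m_per_s, k_m2) |>
  head(3)
#> # A tibble: 3 × 5
#>   sample  trial   t_s K_m_per_s      k_m2
#>   <chr>   <int> <dbl>     <dbl>     <dbl>
#> 1 sample1     1   950  0.000152  1.55e-11
#> 2 sample1     2   890  0.000162  1.65e-11
#> 3 sample1     3   520  0.000277  2.83e-11
```

`K` is the hydraulic conductivity (m/s) from the head drop 0.45 → 0.425 m
over the elapsed time; `k` is the intrinsic permeability (m²) after
removing the fluid properties. `verify_reference_values()` recomputes every
printed number of the record set and reports relative deviations;
`audit_reference_height()` demonstrates numerically that the single-trial
record set's printed sample height is inconsistent with its printed
conductivities by exactly a factor of ten (the package reports, and does
not silently correct, this discrepancy).

Solver verification against closed forms, and a full synthetic
characterization:

```r
# Hagen-Poiseuille: straight channel, r = 16 um in a 64^3 domain
ch  <- generate_channel_phantom(c(64, 64, 64), 1, radius_um = 16, axis = "z")
sol <- solve_stokes_flow(ch, axis = "z", Q_m3_s = 1e-12)
darcy_permeability(sol)$k_m2 / (pi * 16^4 / (8 * 64^2) * 1e-12)
#> [1] 1.0105    # within ~1% of the closed form

# endoneurium-like phantom: porosity target 35.5%, chamber ESD target 11.8 um
ph <- generate_fiber_phantom(phantom_spec(seed = 1))
compute_porosity(ph)
#> [1] 0.3502
esd_distribution(separate_objects(ph, "pore"))$mean_um
#> [1] 13.75     # watershed pore size, um
darcy_permeability(solve_stokes_flow(ph, axis = "z", Q_m3_s = 1e-13))$k_m2
#> [1] 2.21e-13  # m^2, within the 1e-13..1e-11 decade of nerve eECM

# J-curve analysis and stiffness calibration
cv <- generate_stress_strain(curve_spec(linear_modulus_MPa = 38.5,
                                        toe_strain = 0.13, max_strain = 0.4,
                                        n_points = 120))
lr <- linear_region_modulus(cv)
c(modulus = lr$modulus_MPa, toe = lr$toe_strain)
#>  modulus      toe
#>   38.500    0.131

rve <- generate_fiber_phantom(phantom_spec(shape = c(32, 32, 32), seed = 3))
sm  <- calibrate_solid_modulus(rve, lr$modulus_MPa, axis = "z")
homogenize_effective_moduli(rve, as.numeric(sm))$E_MPa
#>    x    y    z
#> 31.1 31.8 38.5   # MPa: stiffer along the channel axis
```

The modulus is recovered exactly on the noiseless curve, the toe strain to
0.13, and the calibrated RVE is transversely isotropic with the
longitudinal direction stiffest — the ordering expected of an aligned
channel microstructure.

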