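Package: poromech
Title: Microstructure, Permeability and Stiffness of Porous Soft-Tissue
    Scaffolds from 3D Voxel Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes anisotropic porous microstructures such as the
    peripheral-nerve endoneurium extracellular matrix from 3D grayscale image
    stacks. Provides threshold calibration and segmentation, representative
    volume element (RVE) selection, voxel morphometrics (porosity, geodesic
    tortuosity, surface area-to-volume ratio, watershed pore and wall sizing
    by equivalent spherical diameter), image-based permeability from a
    staggered-grid Stokes solver with Darcy's law, falling-head permeameter
    reduction, directional effective stiffness by linear voxel
    homogenization, and hyperelastic constitutive fitting (Yeoh,
    Mooney-Rivlin, Ogden, neo-Hookean) of uniaxial tensile curves. Includes
    generators for synthetic phantoms with known ground truth so that every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
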