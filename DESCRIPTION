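Package: hydrosite
Title: Hydration-Site Thermodynamics by Inhomogeneous Fluid Solvation Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes the enthalpic and entropic contributions of individual
    water molecules in protein cavities to the hydration free energy using
    inhomogeneous fluid solvation theory. Water molecules are represented as
    rigid-body poses (position plus orientation quaternion); per-site
    solute-water entropies are estimated nonparametrically from k-nearest-
    neighbour distances in the mixed six-dimensional translation/orientation
    metric, and water-water correlation entropies from a permuted-fill-mode
    mutual-information estimator in twelve dimensions. Includes direct
    Lennard-Jones/Coulomb interaction energies with the TIP4P-2005 water
    model, disjoint-block error estimation, thermodynamic-cycle arithmetic
    with the analytic harmonic-restraint correction, comparison statistics
    against perturbation-based binding free energies, synthetic pose
    generators with closed-form reference entropies, trajectory input from
    PDB/DCD or a plain-text snapshot format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
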