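Package: frpmf
Title: Forward-Reverse Pulling Free Energies and Bilayer Trajectory Observables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the insertion of small aromatic solutes
    (lignin-derived guaiacyl and syringyl units) into ceramide-like lipid
    bilayers at desk scale. Provides an overdamped Langevin generator for
    solute dynamics on a one-dimensional membrane potential, constant-velocity
    steered pulls with on-the-fly work accumulation, a toy bilayer scene
    builder with plantable ground-truth features, readers and writers for PDB
    and multi-frame XYZ trajectories with a small atom-selection language, the
    standard trajectory observables (center-of-mass distance series, number
    density profiles, Shrake-Rupley solvent-accessible surface area, geometric
    hydrogen bonds, distance-cutoff clustering, end-to-end and dihedral
    conformational maps), and the forward-reverse non-equilibrium estimator
    of the potential of mean force, dissipation and position-dependent
    diffusivity from mean pulling works.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
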