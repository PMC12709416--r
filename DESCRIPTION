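Package: cgphase
Title: Residue-Level Coarse-Grained Phase Separation Simulation and
    Condensate Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying liquid-liquid phase separation of
    intrinsically disordered proteins with a one-bead-per-residue
    implicit-solvent model (harmonic bonds, Ashbaugh-Hatch pair
    potential, Debye-Hueckel electrostatics) integrated by BAOAB
    Langevin dynamics in periodic slab geometry.  Includes slab and
    radial density profiles, coexistence-density extraction,
    critical-point fitting with the 3D Ising exponent and the
    rectilinear-diameter law, inter-chain contact maps at residue and
    atomistic resolutions with 1D/region/residue-type reductions,
    geometric detectors for cation-pi, sp2-pi and hydrogen-bond
    interactions, Donnan-style ion-partitioning prediction, and
    seed-deterministic synthetic-data generators for every analysis
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    bio3d,
    yaml
Config/testthat/edition: 3
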