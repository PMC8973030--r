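Package: bindsim
Title: Simulation and Least-Squares Fitting of Protein Binding Equilibria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact and numerical mass-action solvers for four protein
    association systems (homodimerization, 1:1 ligand binding, two ligands
    competing for one receptor, one ligand competing for two receptors),
    thermodynamic conversions between dissociation constants, association
    constants and binding free energies, concentration sweeps with relative
    and absolute scales, pie fractions and concentration tables in molar and
    mass units, and a least-squares tool that estimates dissociation
    constants or total concentrations from titration data by grid search
    (two-pass, single-pass or iterative) or continuous refinement. Includes
    a seeded synthetic-data generator for parameter-recovery testing and a
    command-line interface with CSV, JSON and SVG output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
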