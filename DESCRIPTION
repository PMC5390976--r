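Package: fluxmodes
Title: Elementary Flux Modes and Elementary Flux Vectors for Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact enumeration of elementary flux modes (EFMs) of metabolic
    flux cones and elementary flux vectors (EFVs) of flux polyhedra under
    arbitrary linear constraints. Flux polyhedra (steady-state spaces further
    restricted by flux bounds or general inhomogeneous linear constraints) are
    reduced to flux cones by homogenization and slack variables, the EFMs of
    the augmented cone are enumerated by a rational double-description method,
    and the results are mapped back to bounded and unbounded EFVs. On top of
    the enumeration the package provides the standard pathway-analysis
    applications: support-minimal subnetworks, essential/blocked/coupled
    reactions, linear rate optimization with optimal-face extraction,
    linear-fractional (yield) optimization including detection of unattained
    suprema, knockout filtering, and exact conformal decomposition of flux
    distributions. A definitional brute-force orthant oracle verifies the
    production path on small instances. All arithmetic is exact rational.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
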