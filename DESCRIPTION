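Package: polembed
Title: Polarizable Embedding QM/MM with AMOEBA-Style Induced Point Dipoles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machinery for polarizable-embedding QM/MM calculations in the
    induced-point-dipole (AMOEBA) formulation: fixed atomic multipoles up to
    quadrupoles with generalized Coulomb interaction tensors, Thole-damped
    kernels, the dual direct/polarization induced-dipole linear systems, a
    self-consistent mutual-polarization loop against a pluggable quantum
    mechanical density provider (with a built-in linear-response model QM),
    analytical geometrical gradients with a finite-difference validator, a
    frozen-environment BFGS geometry optimizer, and the state-specific
    correction to state-averaged excitation energies. Includes readers and
    writers for XYZ geometries and a JSON parameter/topology schema, a seeded
    fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
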