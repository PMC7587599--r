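Package: llpsmd
Title: Coarse-Grained Bead-Spring Simulations of Protein Liquid-Liquid
    Phase Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A minimal coarse-grained model for intrinsically disordered
    protein regions (IDRs): flexible Lennard-Jones bead-spring chains with
    tunable bending stiffness and rigid globular variants. Provides a
    compiled molecular-dynamics engine (NVE, NVT with Nose-Hoover chains or
    Langevin dynamics, isotropic pressure control for preparation runs,
    rigid-body propagation), builders for single chains, bulk boxes,
    direct-coexistence slabs and 50:50 binary mixtures, density-profile
    extraction of coexisting densities, critical-point estimation via the
    laws of rectilinear diameters and critical exponents, and per-chain
    conformational observables (radius of gyration, end-to-end distance,
    intra- and inter-molecular contact counts) used to relate the IDR
    conformational ensemble to the stability of liquid-liquid phase
    separation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
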