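Package: ionoslip
Title: Coarse-Grained Molecular Dynamics of Sliding Zwitterionic Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained coarse-grained molecular-dynamics simulator and
    analysis toolkit for the boundary-lubrication problem of two zwitterionic
    head-group monolayers in sliding contact. Builds commensurate rotated
    two-layer systems of tethered seven-bead molecules, evaluates a force
    field of harmonic bonds and angles, shifted Morse pair interactions and
    Ewald-split Coulomb electrostatics with a slab correction, integrates
    Langevin dynamics with anisotropic damping under normal load and a
    spring-driven sliding stage, and computes friction observables: shear
    stress traces, stick-slip versus smooth-sliding regime classification,
    hooking (interpenetration) fraction, interlayer distance, and the
    correlation between potential energy and hooking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
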