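Package: dpdcell
Title: Mesoscopic Dissipative Particle Dynamics Model of Eukaryotic Cell
    Mechanics
Version: 0.1.0
Authors@R:
    person("dpdcell", "developers", email = "dpdcell@example.org",
           role = c("aut", "cre"))
Description: A three-component mesoscopic model of a eukaryotic cell --
    triangulated viscoelastic membranes for the cell surface and nucleus
    envelope, and a cross-linked filament network for the cytoskeleton and
    chromatin -- embedded in a Dissipative Particle Dynamics (DPD) fluid.
    Provides stochastic assembly of the cytoskeleton with Bell-law bond
    kinetics, solid-wall geometries (micropipettes, obstacle arrays) via
    signed distance functions, virtual micropipette-aspiration and
    microfluidic-transit experiments, and the analysis layer (Theret
    half-space modulus, creep viscosity, parameter sweeps) used to probe
    whole-cell viscoelasticity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
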