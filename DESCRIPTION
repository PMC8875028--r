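Package: vesimorph
Title: Monte Carlo Simulation of Vesicle Shaping by an Adsorbing
    Semiflexible Polymer in Two Dimensions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Off-lattice Metropolis Monte Carlo simulator for a soft
    two-dimensional vesicle, modelled as a closed bead-spring ring,
    deformed by an adsorbing semiflexible linear polymer. Bonds are
    finitely extendable nonlinear elastic (FENE) springs, intra-chain
    excluded volume is a short-ranged Morse potential, polymer stiffness
    is an angular bending penalty, and the vesicle-polymer attraction is
    a truncated Lennard-Jones well. Provides exact incremental energy
    bookkeeping, a compiled single-bead-displacement Metropolis engine
    with deterministic per-replica random streams, the standard
    observables (adsorption energy, end-to-end distance, tangent-tangent
    correlation, gyration-tensor asphericity), shape classification of
    the folded vesicle morphologies, quadrature oracles for sampling
    verification, and a sweep driver over bending stiffness and
    adsorption strength grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
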