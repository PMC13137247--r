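Package: petfes
Title: Coarse-Grained Free-Energy Workflows for Crystalline and Amorphous PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale free-energy machinery for studying the conformational
    polymorphism of polyethylene terephthalate (PET) oligomers and its
    thermodynamic consequences for enzymatic depolymerisation. Provides a
    coarse-grained torsional model of a PET tetramer whose gauche/trans
    equilibrium is steered by terminal-distance wall restraints, torsion-space
    Metropolis Monte Carlo, from-scratch well-tempered metadynamics and
    Hamiltonian replica-exchange (solute-tempering) engines, reweighted
    free-energy-surface analysis with block-averaged errors and bound/unbound
    state integration, and the closed-form thermodynamic bookkeeping
    (standard-state corrections, population-depletion factors, per-monomer and
    fold-surface energetics) that connects simulation output to experimental
    scales. Trajectories, bias checkpoints and free-energy profiles are read
    and written in the whitespace-delimited COLVAR table dialect used by
    metadynamics engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
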