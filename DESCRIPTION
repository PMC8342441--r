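Package: conformpath
Title: Conformational Activation Pathways of G-Protein-Coupled Receptors
Version: 0.1.0
Authors@R:
    person("conformpath", "developers", email = "conformpath@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for receptor activation pathways in a
    low-dimensional order-parameter space: overdamped Langevin generators on
    multi-basin model potentials, nudged-elastic-band minimum-energy paths,
    Boltzmann-inversion free-energy landscapes, Markov state models with
    PCCA+ coarse-graining, Chapman-Kolmogorov validation and transition-path
    theory kinetics, time-lagged independent component analysis, and
    operational-model (Black-Leff) quantification of biased signaling from
    dose-response data. Includes PDB reading, Ballesteros-Weinstein residue
    resolution and Kabsch superposition for featurizing experimental
    structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
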