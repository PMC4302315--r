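Package: msmpose
Title: Markov State Model Prediction of Ligand Binding Poses and Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Markov state models (MSMs) from ensembles of
    protein-ligand binding trajectories and uses them to predict ligand
    binding poses and pathways. Implements k-centers clustering with hybrid
    k-medoids refinement under a protein-backbone-aligned ligand RMSD
    metric, maximum-likelihood (reversible) transition-matrix estimation
    with implied-timescale validation, equilibrium-population pose ranking,
    mapping of state probabilities to a 3-D free-energy grid written as
    OpenDX volumetric files, transition-path-theory analysis of binding
    pathways (committors, net fluxes, bottleneck pathway decomposition,
    mean first passage times and association rates), and the adaptive
    sampling workflow around them: convergence monitoring of the
    top-populated pose, MSM-state seed selection, and grid-translation
    pose seeding with steric-clash rejection. Ships ground-truth synthetic
    generators (exact Markov-chain sampling and a Metropolis toy binding
    simulator with designed free-energy wells) so the full protocol can be
    exercised and validated without molecular dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
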