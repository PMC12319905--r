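Package: effint
Title: Effective Interaction Strengths from Liquid-Mixture Simulation Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes species-pair-resolved effective interaction strengths --
    density-weighted integrals of pair potentials over partial radial
    distribution functions -- from particle trajectories of simulated liquid
    mixtures, together with molecular-level aggregates and an effective energy
    of mixing that diagnose mixing versus demixing at the level of individual
    atom-type interactions. Includes readers for extended-XYZ trajectories,
    plain-text topologies and force-field tables (Lennard-Jones 12-6 plus
    Coulomb, with geometric or Lorentz-Berthelot combination rules and
    per-pair overrides), partial radial distribution functions with periodic
    minimum-image distances, a deterministic toy-system generator (slab,
    random-mixture and lattice fixtures), a Metropolis Monte Carlo sampler for
    binary Lennard-Jones fluids, a brute-force pair-energy oracle, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    jsonlite,
    optparse,
    yaml,
    utils,
    stats,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
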