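Package: flipkinetics
Title: Umbrella-Sampling Free-Energy Profiles and Flipping Kinetics for
    Base-Flipping Reaction Coordinates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to reconstruct periodic free-energy profiles from
    umbrella-sampling windows along a base-flipping pseudo-dihedral
    reaction coordinate and to turn them into kinetic estimates. Includes
    a periodic weighted-histogram (WHAM) solver, a free-energy-perturbation
    correction for auxiliary flat-bottom restraints, per-window diffusivity
    estimation from autocorrelation analysis, mean first passage times and
    rates by Smoluchowski double integrals, and an overdamped Langevin
    generator of synthetic umbrella campaigns (with Hamiltonian
    replica-exchange emulation and a brute-force first-passage oracle) for
    end-to-end validation against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    bio3d,
    minpack.lm,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
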