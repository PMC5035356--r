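Package: fluctB
Title: Crystallographic B-Factor Prediction from Replicate MD Trajectory Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts per-atom crystallographic B-factors from ensembles of
    short, independent molecular dynamics trajectories using a two-step
    rigid-body superposition procedure (align all frames to the first saved
    conformation, average, then refit to the average) followed by conversion of
    mean-square atomic fluctuations to B = 8*pi^2*<u^2>. Includes uniform
    atomic-mass scaling utilities (high-mass x100 / low-mass x0.1) with
    sqrt(c) nominal-time conversion and AMBER prmtop MASS-block rewriting, a
    deterministic toy MD engine (velocity Verlet; NVE, Berendsen and Langevin
    thermostats; harmonic-tether and elastic-network potentials; heating
    ramps) with analytic fluctuation oracles, and evaluation of calculated
    against experimental B-factor profiles (RMSD with ensemble standard
    error, Pearson correlation).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
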