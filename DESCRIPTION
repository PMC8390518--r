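Package: cel7track
Title: Single-Molecule Tracking and Three-State Kinetics of Cellulase
    Cel7A on Cellulose
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates, localizes, segments and kinetically models
    single-molecule trajectories of the cellobiohydrolase Cel7A moving on
    immobilized cellulose. Includes a three-state (solution, static,
    processive) stochastic trajectory generator with optional rendering of
    TIRF-like image stacks, sub-pixel 2D Gaussian spot localization with
    fiducial-based drift correction, anchor-based motion-state segmentation
    with jump detection, truncated-exponential dwell-time maximum-likelihood
    fitting with bootstrap confidence intervals, and derivation of the
    three-state rate constants from dwell times and branching fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    tiff,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
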