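Package: ripplephase
Title: Ripple-Band Phase Precession Analysis for Hippocampal Replay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for phase precession of hippocampal place-cell
    firing relative to ripple-band (150-250 Hz) and theta-band (6-12 Hz) local
    field potential oscillations. Detects candidate replay events from
    multi-unit activity or ripple-band power, decodes replayed trajectories
    from population spiking with a Poisson Bayesian decoder assessed against
    cell-identity shuffles, quantifies within-event and within-field phase
    precession with circular-linear regression and permutation phase locking,
    and estimates theta and ripple sweeps from phase-binned decoded or actual
    positions. Includes a synthetic linear-track session generator with known
    ground truth for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
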