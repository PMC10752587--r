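Package: mtcoupler
Title: Mechanical Coupling of Growing Microtubule Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation and trace analysis for microtubule pairs
    growing against a shared elastic load. Implements a Hookean spring-coupler
    force partition, exponential (Bell-type) force-dependent kinetic laws for
    run/pause switching and growth speed, a modified Gillespie simulator with a
    capped timestep for single tips under force clamp and for coupled pairs,
    sliding-window run/pause segmentation of position-versus-time recordings
    with per-recording Gaussian-mixture speed thresholds, force-binned rate
    estimation with exponential force-dependence fits, tip-separation
    statistics for dual-trap recordings, Kaplan-Meier survival and log-rank
    comparison of threshold-exceedance times, and histogram-likelihood
    comparison of pausing versus non-pausing growth models. A synthetic-data
    generator emulates force-clamp and dual-trap recordings so the full
    analysis chain can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
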