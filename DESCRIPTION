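Package: mtmotor
Title: Magnetic-Tweezers Analysis of a Loop-Extruding DNA Helicase-Nuclease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of single-molecule magnetic-tweezers
    experiments on a processive, loop-extruding DNA motor protein, together
    with the bulk enzyme-kinetics fits that accompany such studies. Provides
    worm-like-chain and freely-jointed-chain polymer models for converting
    bead height to base pairs and for Brownian-fluctuation force calibration;
    a Gillespie-style stochastic simulator of unwinding, pausing, backsliding
    and rehybridization on flap-loaded tethers (with optional site-specific
    nicks and single-stranded-DNA-binding protein); trace filtering,
    derivative-threshold event segmentation and dwell-time extraction;
    maximum-likelihood and histogram fits of event-length, rate and dwell
    distributions with Gaussian/gamma and Gaussian/exponential model
    comparison; a hyperbolic estimator of the second-order association rate
    constant; and Michaelis-Menten, substrate-activation and progress-curve
    fitting with matched synthetic-data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    minpack.lm,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
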