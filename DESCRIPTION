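Package: perturbwalk
Title: Margin-of-Stability Analysis of Treadmill Belt-Acceleration
    Perturbations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing dynamic gait stability and perturbation
    recovery on instrumented dual-belt treadmills. Computes the
    anteroposterior margin of stability (MoS) at foot touchdown from a
    reduced six-marker model (C7, sacrum, trochanters, halluces) via the
    extrapolated centre of mass, solves the stability-normalised walking
    speed (the speed at which mean MoS over the final ten steps equals a
    target, default 0.05 m), labels Base/Pre/Post1-8 steps around
    unannounced belt-acceleration perturbations, counts recovery steps
    with a backward band scan, derives spatiotemporal step parameters and
    their coefficients of variation, and runs the associated statistical
    battery (mixed two-way repeated-measures ANOVA, Mann-Whitney,
    Friedman with tie correction, Wilcoxon signed-rank, Monte-Carlo
    Dunnett and Sidak adjustments, effect-size and repeated-measures
    sample-size utilities). A fully labelled synthetic gait generator
    (markers, ground reaction forces, belt-speed commands and ground
    truth) supports validation and power studies without motion-capture
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
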