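Package: sckinetics
Title: Kinetic Analysis of Synaptonemal Complex Assembly and Disassembly
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and quantification of synaptonemal complex (SC)
    dynamics from live-cell 3D time-lapse fluorescence microscopy of
    budding yeast meiosis.  Provides a synthetic-data generator for
    piecewise-linear SC growth programs, nuclear Zip1 expression
    profiles, rendered 3D+time image stacks and telomere-led motion
    tracks; filament detection, tracing and length measurement in image
    stacks; continuous segmented (piecewise-linear) regression of
    length-versus-time trajectories with model selection by adjusted
    R-squared and the leave-one-out PRESS statistic; classification of
    assembly, final-disassembly and abortive-disassembly events in the
    context of nuclear Zip1 levels; and the closed-form statistics used
    in this analysis (Poisson multiple-initiation model, binomial miss
    probability, two-proportion z test, Welch t test, two-means velocity
    clustering).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
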