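Package: nirslat
Title: Hemispheric Lateralization Analysis of Prefrontal fNIRS Stress Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-related analysis pipeline for two-wavelength functional
    near-infrared spectroscopy (fNIRS) recordings of the prefrontal cortex in
    stress paradigms. Converts optical-density changes to oxy- and
    deoxyhemoglobin concentration changes with the modified Beer-Lambert law,
    applies zero-phase Chebyshev band-pass filtering in second-order sections,
    segments and baseline-corrects task-locked epochs, and computes the
    laterality index for stress (LIS) from right- and left-hemisphere channel
    sets. Includes salivary alpha-amylase based group assignment
    (control/eustress/distress), the associated group-comparison statistics
    (Levene, t-test, one-way ANOVA, Dunnett T3 post hoc, Pearson correlation),
    and a synthetic-data generator that emulates the stimulus-response
    paradigm, cohort structure, and lateralized hemodynamic responses so the
    whole pipeline is testable without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    car,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
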