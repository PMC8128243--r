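Package: vaeframes
Title: Reference-Frame Analysis of the Ventriloquism Aftereffect
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how eye- and head-centred visual reference
    frames drive audio-visual spatial recalibration (the ventriloquism
    aftereffect). Generates adaptation/test schedules for blocked fixation
    x duration x disparity designs, synthesizes spatialized auditory
    stimuli (band-limited pink noise, amplitude modulation, raised-cosine
    gating, image-source room reverberation, spherical-head binaural
    filters), simulates parametric observers with adaptation dynamics and
    outlier contamination, and runs the two-level analysis: robust
    Mahalanobis outlier rejection, per-condition bias/gain regression,
    disparity contrasts, repeated-measures and mixed ANOVAs with
    Greenhouse-Geisser correction and generalized eta-squared, polynomial
    contrasts, Hedges g_av, JZS Bayes factors, and noncentral-t power
    computations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
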