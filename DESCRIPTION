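Package: sleepart
Title: Multidimensional Sleep-Health Trajectories Across Cognitive-Aging Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the amount, regularity, and timing ("ART")
    of sleep change across three cognitive-aging pathways (normal aging,
    stable mild cognitive impairment, and progression to dementia) in
    longitudinal cohorts of older adults. Provides wrist-actigraphy
    preprocessing (nonwear exclusion, FIR downsampling, rest-interval
    detection, valid-day accounting), parametric and nonparametric
    rest-activity rhythm features (extended sigmoidally transformed cosine
    model, interdaily stability, intradaily variability), pathway assignment
    from annual diagnosis sequences, weighted linear mixed-effects models with
    truncated cubic-spline knots at subject-specific diagnosis onset ages,
    backward term elimination, standardized benchmark-age contrasts with
    Benjamini-Hochberg correction, and a seeded synthetic-cohort generator for
    validating every stage against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
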