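Package: ivdnet
Title: Sex-Stratified Trait Correlation Networks for a Rat Annular-Puncture
    Disc Degeneration Study
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a 2x2 (sex x injury)
    preclinical study of lumbar intervertebral disc (IVD) degeneration and
    pain in the rat annular-puncture model. Provides a seeded synthetic study
    generator (creep and cyclic biomechanical traces, von Frey filament
    response tables, DRG qPCR Ct values, radiographic IVD heights, histology
    subscores), reduction of raw signals to endpoint traits (5-parameter
    viscoelastic creep fit, 20th-cycle axial and torsional properties, paw
    withdrawal thresholds, delta-Ct relative expression with ROUT outlier
    removal, IVD-height percent change, degeneration grades), two-way ANOVA
    with Tukey post-hoc group statistics, and sex-stratified Spearman
    correlation networks with Benjamini-Hochberg false discovery rate
    control, including a Fisher-z power calculation for correlation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    car,
    igraph,
    jsonlite,
    yaml,
    rlang,
    tibble,
    dplyr,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    withr,
    optparse
Config/testthat/edition: 3
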