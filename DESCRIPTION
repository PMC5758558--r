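Package: yeastlab
Title: Morphometry, Growth Kinetics and Individual-Based Simulation of
    Budding-Yeast Batch Cultures
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse Saccharomyces cerevisiae batch cultures at two
    levels of observation. At the population level, the three-phase piecewise
    linear (Buchanan) primary growth model is fitted to log10 cell-density
    curves and used to label sampling times with a growth phase (lag, log,
    stationary). At the individual level, a microscopy image-analysis
    pipeline segments bright-field micrographs of yeast cells, measures
    direct (area, perimeter, major and minor diameter) and derived
    (circularity, elongation) morphometric parameters, and classifies budded
    versus unbudded cells; a ground-truthed synthetic scene generator
    supports validation. A statistical battery (chi-square independence,
    Bonett-gated two-sample t tests, Welch ANOVA with Games-Howell post hoc
    and compact letter display, quadratic discriminant allocation) compares
    groups of cells and kinetic parameters. A stochastic individual-based
    simulator of aerobic and microaerophilic yeast batch cultures produces
    population time series and single-cell size snapshots on the same schema,
    so simulated and observed distributions can be compared directly.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    MASS,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
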