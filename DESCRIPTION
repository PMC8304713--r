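Package: solvscreen
Title: Solvent Screening for Drug Solubility with Segment-Interaction
    Descriptors and Ensembles of Small Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for ranking candidate solvents for a poorly soluble
    drug from solid-liquid-equilibrium thermodynamics and machine
    learning.  Provides a toy COSMO-RS-style segment thermodynamics
    engine (misfit, hydrogen-bond and van der Waals pair energies,
    self-consistent sigma-potentials, mean interaction energies), an
    iterative solubility solver with pluggable activity-coefficient
    models, seven-descriptor feature construction with mole-fraction
    mixing for multicomponent solvents, ensembles of single-hidden-layer
    perceptrons with explicit acceptance criteria and range-filtered
    averaging, leverage-based applicability-domain diagnostics (Williams
    plot data), candidate enumeration for neat solvents, aqueous binary
    mixtures and deep-eutectic formulations, and a seeded synthetic-data
    generator so the full pipeline is testable end to end.  Ships the
    experimental theophylline mole-fraction solubilities used throughout
    as a packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
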