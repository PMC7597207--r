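Package: cellscale
Title: Multi-Scale Agent-Based Simulation of Bacterial Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular engine for composing heterogeneous models of cellular
    processes into integrated, multi-scale simulations of bacterial agents.
    Processes (mechanistic sub-models running at their own time-steps) are
    wired through ports to hierarchical stores of state variables, with
    declarative updaters, dividers and emitters. Ships process libraries for a
    2D colony environment (overdamped capsule mechanics, reaction-diffusion
    nutrient fields), exponential growth and mass-threshold division, dynamic
    flux balance analysis coupled to convenience-kinetics membrane transport
    (glucose-lactose diauxie), sequence-based stochastic gene expression
    (Gillespie transcription, translation, complexation and degradation with
    explicit nucleotide, amino-acid and ATP accounting; a flagellar regulon
    fixture demonstrating just-in-time expression), and the chemotaxis
    sensorimotor chain (Goldman-equation proton-motive force,
    Monod-Wyman-Changeux chemoreceptor cluster with methylation adaptation,
    CheY-P signal transduction, bistable flagellar switching, and run-and-
    tumble motility with veto aggregation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
    jsonlite,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
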