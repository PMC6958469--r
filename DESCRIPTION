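Package: ttcsynergy
Title: Combination-Synergy Analysis for Targeted Alpha Therapy plus PARP Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative analysis pipeline for preclinical combination studies
    of a targeted thorium-227 conjugate (TTC) with a PARP inhibitor. Implements
    fixed-ratio Chou-Talalay median-effect combination-index analysis of
    viability plates (four-parameter logistic fits, absolute IC50,
    isobologram coordinates), Bliss-additivity synergy calling on xenograft
    treatment-over-control ratios with one-way ANOVA/Tukey significance,
    radiometric arithmetic (decay correction, percent injected activity per
    gram, Bateman daughter ingrowth, specific activity, activity-to-molarity
    conversion), and seed-reproducible synthetic-data generators for every
    input table so the full pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
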