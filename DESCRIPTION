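Package: meltshift
Title: Thermal Proteome Profiling and Drug-Resistance Proteomics Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dissecting drug resistance in cancer cell
    lines from multi-layer proteomics data. Implements thermal proteome
    profiling (TPP) melting-curve sigmoid fitting at protein or peptide level,
    replicate-concordant melting-point shift (delta-Tm) hit calling,
    Perseus-style two-group differential analysis of label-free proteomes and
    phosphoproteomes with subtractive and intersection set logic for kinase
    triage, hypergeometric over-representation of kinase-substrate and
    transcription-factor target libraries, zero interaction potency (ZIP)
    drug-synergy scoring of dose-response matrices, and grouped gene-gene
    co-expression ranking. A seeded synthetic-data generator emulates every
    input with recorded ground truth, so each stage is testable against
    planted structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
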