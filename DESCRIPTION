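Package: coilface
Title: Interface Characterization and Binding Analysis for Predicted
    Coiled-Coil Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Confidence-aware interpretation of predicted protein complex
    models and quantitative surface plasmon resonance (SPR) binding
    analysis, developed around the 2:1 Trim28 coiled-coil / KRAB domain
    interface. Provides pLDDT-based model pruning and PAE block summaries,
    Kabsch rigid-body superposition with all-equivalent-atom RMSD, a
    deterministic Shrake-Rupley solvent-accessible surface area engine,
    buried-surface-area and typed contact / hydrophobic-cluster /
    pin-residue interface reports, steady-state and two-state kinetic SPR
    fitting with mutant fold-decrease tables, and synthetic structure and
    sensorgram generators with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    bio3d,
    minpack.lm,
    deSolve,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
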