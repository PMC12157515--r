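Package: lhldesign
Title: Geometry, Diversity and Stability Analysis for Loop-Helix-Loop
    De Novo Protein Design Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the geometric diversity of de novo
    designed alpha-beta proteins whose loop-helix-loop (LHL) elements have
    been reshaped against a fixed beta sheet. Provides backbone PDB input
    and output with segment annotations, Kabsch superposition, the
    sheet-aligned pairwise helix RMSD and reshaped-LHL RMSD metrics, 6D
    helix-vector geometry bins, shell-residue and sheet-face
    classification, prediction-bias statistics, structure-similarity-aware
    train/test splitting by spectral clustering with leakage pruning,
    scramble negative-control sequence generation, metric-threshold design
    selection, protease-resistance (EC50) stability classification against
    scramble-derived thresholds, and a synthetic-data generator that
    emulates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
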