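Package: gtusc
Title: Interface Contact Persistence, Fragment Screening and Thermal-Shift
    Analysis for gamma-Tubulin Complex Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing pipeline for structure-based screening of the
    GCP4/gamma-tubulin protein-protein interface. Reads multi-model PDB
    trajectories and PDBQT docking pose files, detects persistent
    intermolecular atom contacts across molecular dynamics frames, computes
    superposition-corrected RMSD series and greedy frame clustering, applies
    Lipinski-style physicochemical filters to fragment libraries, clusters
    and ranks docking poses, enumerates binding-pocket residues, and fits
    differential scanning fluorimetry melt curves with the four-parameter
    Boltzmann sigmoid to classify thermal-shift screens. A synthetic-data
    module generates every input format with machine-readable ground truth
    so each stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
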