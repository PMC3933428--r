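Package: bivalens
Title: Valency Classification of Receptor Homodimer Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies conformations of a homodimeric cell-surface receptor
    as monovalent-only or bivalent-competent. An elongated two-domain ligand
    is placed onto each monomer of every dimer conformer by rigid
    template-based docking (Kabsch superposition of a binding-mode template),
    the solvent-accessible surface area buried between the two docked
    ligands' membrane-proximal domains is computed by the Shrake-Rupley
    algorithm, and frames with zero buried surface are scored as
    bivalent-competent. Includes multi-model PDB input/output with atom
    selections, dimer-geometry descriptors (opening angle, binding-site
    separation), constructions of reoriented and template-grafted dimer
    conformations, per-trajectory and cross-trajectory bivalent-fraction
    summaries, and a seeded synthetic toy-dimer ensemble generator with
    closed-form ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
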