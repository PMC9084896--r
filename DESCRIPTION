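Package: confhet
Title: Side-Chain Conformational Heterogeneity in Multiconformer Crystal Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies protein side-chain conformational heterogeneity in
    multiconformer crystallographic models and compares matched ligand-bound
    (holo) and ligand-free (apo) structures. Provides altloc-aware PDB input
    and output, chi1 angular and harmonic (B-factor) order parameters with
    resolution normalization, occupancy-weighted side-chain RMSF and
    B-factors, rotamer-well assignment and apo/holo rotamer-change
    classification, geometric hydrogen-bond detection on altloc-split models,
    Shrake-Rupley solvent accessibility, binding-site and distant-residue
    partitioning, cohort-level paired statistics (matched controls, residual
    regression, bootstrap slope comparison, quartile tests), and a synthetic
    multiconformer-structure generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
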