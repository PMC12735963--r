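Package: conflock
Title: Conformational-Ensemble Analysis of Ligand-Induced Locking in
    Protein Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies ligand-induced "conformational locking" from molecular
    dynamics trajectory ensembles. Provides trajectory and topology readers
    (multi-model PDB, DCD, XTC), an atom-selection mini-language, Kabsch
    superposition and stability metrics (RMSD, radius of gyration, RMSF),
    dynamic cross-correlation matrices reduced to domain-level allosteric
    networks, Calpha principal-component projections with k-distance-calibrated
    DBSCAN state censuses and Gibbs free-energy landscapes, protein-ligand
    interaction-fraction analysis, replicate-level MM/GBSA statistics, and a
    seeded synthetic-ensemble generator with planted metastable states,
    correlation blocks and pseudo-ligand contacts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
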