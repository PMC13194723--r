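Package: helixgate
Title: Helix Geometry, Ligand Engagement and Ensemble Analysis for
    Transporter MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-processing toolkit for molecular-dynamics studies of
    ligand-gated membrane transporters. Computes HELANAL-style local
    helical twist from sliding 4-Calpha windows, per-residue deviation
    maps from ideal alpha-helical geometry and their time integrals,
    ligand-helix hydrogen-bond engagement series with categorical
    binding-fate calls, per-residue protein-ligand interaction
    fingerprints averaged over replicates, pooled-trajectory principal
    component analysis with loop-state classification, gromos-style RMSD
    clustering with cluster-median representatives, and static-structure
    comparisons (Calpha RMSD, binding-site shells, contact distances,
    sequence identity and similarity). Ships seeded synthetic-trajectory
    generators (helix unwinding, loop flipping, ligand engagement) with
    known ground truth so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
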