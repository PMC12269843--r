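Package: tcrint
Title: Interface Analysis and Binding Models for TCR-Peptide-MHC Class II Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative characterization of T cell receptor (TCR) recognition
    of peptide-MHC class II complexes from crystal structures and binding
    assays. Parses PDB/mmCIF structures, assigns chain roles, IMGT regions and
    the peptide pocket register (P-2 to P9), and detects the HLA-DRB1 shared
    epitope motif. Computes Shrake-Rupley solvent-accessible surface area,
    buried surface area decomposed by CDR loop and framework region,
    distance-criterion contact tables (hydrogen bonds, van der Waals, salt
    bridges, disulfides), TCR docking-angle geometry and Kabsch superposition
    r.m.s.d. Fits steady-state surface plasmon resonance binding curves
    (one-site model) and fluorescence-polarization competition curves
    (four-parameter logistic), and classifies mutational impact by affinity
    fold change. Includes synthetic-data generators with analytic ground truth
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
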