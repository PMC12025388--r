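Package: rhconf
Title: Conformer Ensemble Analysis for Rh-Bisphosphine Catalyst Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for substrate-aware analysis of conformer ensembles of
    rhodium-bisphosphine catalyst complexes. Reads CREST-style multi-frame
    XYZ ensembles and per-conformer property tables, splits complexes into
    ligand and substrate fragments, computes minimal heavy-atom RMSD
    profiles by Kabsch superposition, filters and deduplicates ensembles,
    evaluates percent-buried-volume steric descriptors on a numerical grid,
    and summarizes steric and electronic descriptors as group-wise
    Boltzmann-weighted means with weighted standard deviations. Includes a
    synthetic-ensemble generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    bio3d
Config/testthat/edition: 3
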