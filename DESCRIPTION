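Package: pocketdyn
Title: Dynamic Descriptors of Protein-Ligand Binding Pockets from MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes per-residue and per-ligand dynamic descriptors of
    protein-ligand complexes from molecular dynamics trajectories: RMSD
    fluctuation ranges after Kabsch superposition, per-residue
    solvent-accessible surface area (Shrake-Rupley) extrema, hydrogen-bond
    existence matrices with three-cluster occupancy classification,
    binding-pocket residue composition and enrichment against the whole-protein
    background, and cohort box-plot statistics.  A benchmark scorer compares a
    complex's descriptors against published cohort reference ranges to grade
    the reliability of a docking pose.  Includes a deterministic synthetic-MD
    generator with known ground truth for end-to-end validation, plus a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), bio3d, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
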