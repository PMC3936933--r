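Package: molscene
Title: Headless Visualization Toolkit for Protein-Ligand Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Parses PDB and PDBQT (AutoDock-family dialect) structures into
    tidy atom tables, builds triangulated macromolecular surfaces (van der
    Waals, solvent accessible, solvent excluded and molecular) by exact
    Euclidean distance transform on a capped voxel grid, detects putative
    intermolecular hydrogen bonds by a heavy-atom distance criterion,
    derives cubic docking search boxes from the largest co-crystallized
    ligand, and renders line/stick/sphere/ribbon representations with
    per-atom color schemes to PNG through a deterministic software
    rasterizer with perspective and orthographic cameras and anaglyph
    stereo compositing. Includes deterministic synthetic-structure
    generators so the whole pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    png,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
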