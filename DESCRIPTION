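Package: isletmap
Title: Single-Islet Histopathology Analysis of Pancreatic Tissue Sections
Version: 0.1.0
Authors@R: person("isletmap", "developers", email = "isletmap@example.org",
    role = c("aut", "cre"))
Description: A semi-automated, single-islet analysis pipeline for multiplexed
    immunohistochemistry of pancreatic tissue sections across stages of type 1
    diabetes. Builds islet objects from co-registered hormone stain masks and a
    parenchymal tissue polygon, quantifies per-islet hormone staining areas,
    classifies islet subsets (insulin-deficient, glucagon-deficient,
    PPY-dominant), attributes CD45+ immune cells to intra- and peri-islet
    compartments and automates the consensus insulitis diagnosis, phenotypes
    single islets by UMAP embedding with two-round DBSCAN clustering (plus a
    deterministic rule-based key), and computes boundary-corrected spatial
    statistics (a modified Ripley's K weighted by the tissue polygon, fractal
    dimension, and radius-pruned Delaunay neighborhood metrics). A synthetic
    cohort generator emulating stage-dependent islet statistics makes every
    stage testable without access to donor material.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
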