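Package: tboscreen
Title: Cell-Type-Resolved Quantification of 3D Organoid Drug Screens and
    Tumor Cell-State Fidelity
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for tumor-forebrain-organoid (TBO) drug
    screening and model-fidelity assessment.  Quantifies multi-channel 3D
    confocal stacks of cleared organoids by compartment-specific summed
    brightness (tumor marker within segmented tumor areas, neuronal marker
    over the whole organoid), turns per-organoid measurements into per-drug
    normalized tumor and tumor-microenvironment effects with exact Wilcoxon
    rank-sum tests and Benjamini-Hochberg hit calling, builds per-compartment
    dose-response curves and derives the therapeutic window (doses with
    significant tumor reduction but no significant neuronal reduction).  A
    transcriptomic arm classifies single tumor cells into radial-glia-like,
    neuronal-progenitor-like, neuroblast-like or undifferentiated states via
    bin-matched signature module scores, and scores how faithfully a culture
    model recapitulates primary-tumor heterogeneity through state
    proportions, cycling fractions, pseudobulk Pearson correlation and
    differential expression.  Ships synthetic generators (organoid image
    phantoms with voxel-level ground truth; negative-binomial single-cell
    count matrices with known states) so every stage is testable by
    parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Matrix,
    fgsea,
    jsonlite,
    methods,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
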