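Package: spatroi
Title: Transcript-Density ROI Differential Expression for Imaging
    Spatial Transcriptomics
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for sub-regional analysis of imaging-based spatial
    transcriptomics sections. Aggregates 2x2 micron high-resolution
    spatial gene-expression bins to segmented nuclei (with size/UMI
    filtering and mitochondrial-gene removal), partitions tissue domains
    from the spatial co-expression of two marker genes, places
    area-standardized regions of interest, and tests per-gene transcript
    densities between two groups with a variance-gated Student/Welch
    t-test, Benjamini-Hochberg adjustment, and volcano classification.
    Includes a seeded synthetic-section simulator (inhomogeneous Poisson
    transcripts, bin grids, nuclei label masks) with known ground truth
    for end-to-end validation, plus a generic hypergeometric
    over-representation test for user-supplied gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Matrix,
    graphics,
    grDevices,
    jsonlite,
    methods,
    pracma,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
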