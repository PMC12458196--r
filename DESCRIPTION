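Package: cryoclone
Title: Mitochondrial Single-Cell Genotyping, Ambient Background Removal,
    Donor Demultiplexing and Clonal Tracing
Version: 0.1.0
Authors@R:
    person("Cryoclone", "Developers", email = "cryoclone@example.org",
           role = c("aut", "cre"))
Description: Tools for clonal analysis of droplet-based single-cell
    mitochondrial genotyping data (mtscATAC-seq style base-count tensors).
    Provides readers and writers for strand-specific per-cell base-count
    tables, cell-level quality filtering, per-cell heteroplasmy estimation
    with variant-confidence metrics (confidently detected cells, strand
    concordance, variance-to-mean ratio), an empty-droplet ambient
    background model with per-cell contamination correction, donor
    demultiplexing from homoplasmic germline variants, clone definition by
    allele-frequency binarization with Jaccard/Ward clustering,
    Kruskal-Wallis lineage-bias testing, and a synthetic droplet-experiment
    simulator with ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
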