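Package: tmbforge
Title: Tumor Mutational Burden from Tumor-Only Panel Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes tumor mutational burden (TMB) from targeted-panel
    variant calls in both matched tumor/normal and tumor-only designs.
    Implements a hard-coded false-positive variant filter engine
    (basic/hotspot/false-positive-database/normal filter predicates), a
    somatic-germline-zygosity (SGZ) classifier built on a purity/ploidy
    copy-number log-ratio model with grid-search estimation, a
    panel-of-normals background library for recurrent germline removal in
    tumor-only mode, TMB computation over a BED-defined panel footprint,
    and survival-based TMB cutoff determination (ROC/Youden with log-rank
    corroboration, Kaplan-Meier and Cox analyses). A seeded synthetic
    cohort simulator with known somatic/germline truth provides the test
    bed, and a command-line entry point wires the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    rtracklayer,
    survival,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
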