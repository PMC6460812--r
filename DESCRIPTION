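Package: dmrflux
Title: Differential Methylation, DMR Calling and Mitochondrial Flux
    Metrics for Two-Group Exposure Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-alignment analysis of reduced representation bisulfite
    sequencing (RRBS) count data for two-group exposure designs: coverage
    filtering, per-CpG beta-binomial Wald tests with Benjamini-Hochberg
    adjustment, rule-based calling and merging of differentially
    methylated regions (DMRs), global methylation histograms and an exact
    binomial test for directional skew, genomic-context annotation of
    DMRs against a gene model, and linkage of DMRs to differentially
    expressed genes within a genomic window. Also computes mitochondrial
    stress-test metrics (basal and maximal respiration, ATP production,
    spare capacity, coupling efficiency) from extracellular-flux oxygen
    consumption traces, and qPCR 2^-ddCT fold changes. A synthetic-data
    module generates methylomes, gene models, expression tables and flux
    plates with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
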