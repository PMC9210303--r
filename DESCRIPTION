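Package: peakforge
Title: Consensus Peaks, Library QC and Differential Accessibility for Developmental ATAC-Seq Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment analysis toolkit for paired ATAC-Seq/RNA-Seq
    developmental studies. Builds consensus open-chromatin peak sets from
    per-sample peak calls (gap merging with per-peak sample support, support
    filtering, shared versus size-class-specific separation), computes ENCODE
    style library quality metrics (TSS enrichment score, FRiP, NRF, PCR
    bottlenecking coefficients, nucleosome-free-region score, fragment size
    distribution, binned coverage correlation), normalizes fragment counts and
    ordinates samples by non-metric multidimensional scaling (Kruskal stress,
    isotonic regression) and PCA, tests differential accessibility and
    expression with negative-binomial likelihood-ratio tests under
    Benjamini-Hochberg FDR control, annotates peaks to genomic features, and
    overlays size-class-specific peaks onto differentially expressed genes by
    signed distance. A seeded synthetic-data generator emulating an unbalanced
    five-stage, three-size-class muscle development design makes the whole
    pipeline testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    MASS,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    cluster
Config/testthat/edition: 3
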