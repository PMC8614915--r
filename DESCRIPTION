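Package: frontloadr
Title: Dual-Genotype Nitrogen-Deficiency Transcriptome Analysis and
    Frontloaded Gene Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for comparing the transcriptional
    response to nitrogen deficiency between two near-isogenic lines (NILs).
    From gene-level RNA-seq count matrices for two genotypes under two
    nitrogen levels, it performs per-contrast differential expression,
    four-contrast Venn set algebra with direction-consistency bookkeeping,
    and the classification of genotype-specific nitrogen-responsive genes
    into "frontloaded" and "relatively upregulated" classes via
    fold-change-ratio rules.  Includes a negative-binomial count simulator
    with planted gene archetypes and ground truth, FPKM and sequencing-QC
    arithmetic, generic hypergeometric term enrichment, and 2^-ddCt
    qPCR-concordance utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    limma
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
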