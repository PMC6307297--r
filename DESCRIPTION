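Package: heartlnc
Title: Identification and Genomic-Context Classification of Heart-Expressed
    Spliced lncRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for identifying spliced, tissue-selective long
    non-coding RNA (lncRNA) candidates from assembled transcript models and
    classifying them by genomic context relative to protein-coding genes
    (bidirectional/divergent promoter, antisense overlap, intergenic).
    Includes the downstream statistics used in developmental-heart lncRNA
    screens: TSS-to-nearest-gene distance distributions with Mann-Whitney
    comparisons, Pearson correlation of divergent promoter pairs across
    developmental stages, hypergeometric enrichment of bidirectional-lncRNA-
    bearing genes among haploinsufficient genes with a housekeeping-gene
    control, generic hypergeometric gene-set enrichment with BH correction,
    and an assembly-fidelity QC based on an exponential fit of exon-number
    error against expression level. A synthetic-data module plants ground
    truth (genomic geometry, tissue-selective expression, divergent-pair
    coupling, enrichment odds) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    jsonlite,
    minpack.lm,
    graphics,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
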