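Package: wingpattern
Title: Differential Expression Pipeline for Butterfly Pupal Wing Microarrays
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable, testable implementation of a transcriptome-microarray
    analysis for identifying proximal-distal prepattern genes and
    color-pattern-specific genes in developing Heliconius erato pupal wings.
    Provides a seeded synthetic probe-level data generator emulating the
    factorial forewing and hindwing designs, spatial quality-control masking,
    log2 loess normalization and probe-to-contig summarization, per-contig
    factorial ANOVA with within-stage pairwise contrasts under FDR control, a
    capped Fisher's-method color-consistency score, correlation-modularity
    gene clustering with a phenotype-consistency filter, and end-to-end
    parameter-recovery reporting against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    jsonlite,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
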