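Package: tespread
Title: Quantifying the Spread of Repressive Chromatin from Transposable Element Insertions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the epigenetic effects of transposable element
    (TE) insertions from ChIP-seq fold-enrichment tracks: windowed two-strain
    and single-genome tests for spreading of H3K9me2 into flanking euchromatin,
    TE catalog curation, gene-level allele z-scores, population presence/absence
    calling from contig alignment spans with family-aware frequency regressions,
    heterochromatin-enriched k-mer quantification across species, and rank-based
    cross-species expression comparison. Includes a synthetic-data generator
    with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    Biostrings,
    MASS,
    nlme,
    lme4,
    limma,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
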