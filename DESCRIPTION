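Package: methperm
Title: Differentially Methylated Regions with a Quadratic-Assignment
    Permutation Null
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of whole-genome bisulfite sequencing count data for
    small replicated designs: per-CpG methylation calls against a lambda
    spike-in nonconversion null (exact binomial test, Benjamini-Hochberg
    FDR), strand merging and hemimethylation diagnostics, gene-body
    methylation levels, fixed 200 bp window differential-methylation-region
    (DMR) calling with a replicate-aware binomial likelihood-ratio test,
    and a quadratic-assignment permutation null that re-runs the full DMR
    analysis under every balanced sample relabeling and builds an exact
    (Poisson-binomial) or Monte-Carlo null for the genome-wide DMR count.
    Includes gene-set intersection and enrichment utilities, a
    methylation-expression correlation, DMR-splice-event spatial overlap,
    and a synthetic-methylome generator with known ground truth that
    emulates sparse mosaic hymenopteran gene-body methylation.
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
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
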