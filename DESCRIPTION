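Package: lncscreen
Title: Cis Co-Expression Screening of Long Non-Coding RNAs in Count-Based
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling the biotype composition of a bulk
    count-based transcriptome, screening long non-coding RNAs (lncRNAs)
    for cis co-expression with their nearest or overlapping protein-coding
    gene using an analytic Pearson critical value, and calling
    differential expression between two sample groups with simple
    count-based callers combined by a multi-caller intersection rule.
    Includes CPM normalization with a mean-expression filter, stranded
    promoter-window and positional-class annotation of lncRNAs, enhancer
    transcription flags from BED intervals, auxiliary metabolic-phenotype
    formulas (lipid derivation, tolerance-test AUC, delta-delta-Ct, daily
    dose from fluid intake), and a seeded negative-binomial synthetic-data
    generator with planted co-expression and differential-expression
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    pracma,
    stats,
    utils,
    tools,
    methods
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
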