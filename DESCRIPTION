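Package: crossarray
Title: Two-Colour Microarray Differential Expression and Cross-Treatment
    Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses two-colour spotted microarray experiments
    with dye-swap designs: spot-level simulation with intensity-dependent dye
    bias and print-tip block effects, loess normalization and block median
    centering, dye-swap averaging, a pooled trimmed-variance paired t
    statistic with Bonferroni control, cross-treatment contingency tables
    with observed/theoretical enrichment ratios and Pearson chi-squared
    tests, triple-overlap expectations, Venn and hypergeometric gene-set
    overlaps, transcriptome signature correlation ranking against an
    expression compendium, and exhaustive promoter k-mer over-representation
    testing with greedy IUPAC consensus clustering and catalogue matching.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    limma,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stringi
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
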