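Package: mutcontext
Title: Context-Dependent Mutation Bias Estimation from Polarized SNPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates context-dependent point-mutation biases from human
    single-nucleotide polymorphisms polarized against two outgroup genomes
    (chimpanzee and orangutan). Implements the mutation-context algebra over
    contiguous 1-6 bp words (subcontext enumeration, reverse-complement
    pairing), seven-rule SNP inclusion filtering with genomic-region
    exclusion, per-context mutation counting with flank-interval or
    whole-genome word-frequency backgrounds, the contrast / minimal-contrast /
    mutation-bias statistics with exact binomial significance and Bonferroni
    control, distribution summaries (bias versus minimal-contrast scatter,
    normal approximation of minimal contrasts), and a seeded forward
    simulator of context-biased mutagenesis that emits the same input formats
    so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
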