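Package: redpanda
Title: Variant Calling for Single-Cell RNA-Seq by Allele-Fraction Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies single-nucleotide variants and micro-indels in single-cell
    RNA sequencing (scRNA-seq) data by partitioning candidate sites into three
    classes: homozygous-looking sites (all reads support the alternate allele),
    heterozygous sites whose allele fractions follow the bimodal distribution
    imposed by allele-specific transcript expression, and the remaining
    heterozygous sites. Bimodally distributed heterozygous variants on the same
    expressed isoform are filtered jointly against the isoform's modal allele
    fraction; homozygous-looking variants are filtered by read depth; the rest
    are confirmed by an external caller's VCF or an internal binomial error test.
    Also provides a variant spike-in simulator that plants truth variants of the
    three classes into alignments under depth and expression constraints, a
    from-scratch fixture generator, and evaluation utilities (confusion counts,
    sensitivity, positive predictive value, pairwise cell overlap, ensemble
    intersection, and per-cell quality-control filters).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
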