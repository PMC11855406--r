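Package: codonbias
Title: Codon Usage Bias Analysis for Chloroplast Protein-Coding Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of synonymous codon usage in organellar (chiefly
    chloroplast) protein-coding gene sets: CDS extraction from GenBank
    flat files or FASTA with strand- and exon-aware location handling,
    quality filtering of coding sequences, relative synonymous codon
    usage (RSCU), positional GC composition (GC1/GC2/GC3/GC3s), Wright's
    effective number of codons (ENC) with its mutation-only expectation,
    neutrality-plot regression, ENC-plot ratio classification, parity
    rule 2 (PR2) bias coordinates, Pearson correlation of composition
    parameters, and optimal-codon identification from high- and
    low-expression gene pools via delta-RSCU. Includes a seeded
    synthetic coding-sequence generator with mutation, selection and
    planted-optimal regimes so every stage can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
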