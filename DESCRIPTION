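Package: kakspipe
Title: Reciprocal-Homologue Ka/Ks Estimation, Tiered SNP Discovery and
    Expression-Bias Selection Tests for Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale comparative molecular-evolution pipeline for de novo
    transcriptome assemblies. Pairs transcripts between two assemblies by
    six-frame translated local alignment and reciprocal best hits, trims each
    pair to the overlapping hit region, threads codons through a global protein
    alignment, and estimates Ka/Ks with the counting method of Nei and Gojobori
    (1986) with Jukes-Cantor correction. Also provides tiered single-nucleotide
    polymorphism discovery from per-position base-count pileups (depth,
    minor-allele-frequency, flanking-distance and homopolymer filters with
    transition/transversion classification), rank tests and general linear
    models linking horn- and morph-biased gene expression to signatures of
    positive and relaxed selection, and seeded generators of synthetic coding
    sequences, expression tables and pileups for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
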