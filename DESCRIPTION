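Package: kmerqc
Title: K-mer Distribution Quality Control for Shotgun Metagenomic Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quality assessment of raw shotgun metagenomic sequence data from
    canonical k-mer distributions. Counts overlapping k-mers in FASTA, FASTQ
    and colour-space (CSFasta) reads with reverse-complement (canonical)
    aggregation, scores samples by the normalized Shannon entropy of the
    k-mer spectrum, flags aberrant k-mers against a reference sample, detects
    and removes barcode-cassette (adapter self-ligation) contamination,
    clusters tetranucleotide profiles by Ward's method with objective
    cluster-count selection and k-means cross-validation, and ships a seeded
    synthetic generator of genomes, metagenome mixtures and dilution series
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    methods,
    tools,
    jsonlite,
    ape,
    Biostrings,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
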