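Package: spaceracq
Title: CRISPR Spacer Acquisition Analysis from Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of spacer acquisition efficiency in type I-E CRISPR-Cas
    systems from amplicon sequencing of expanded CRISPR arrays. Extracts newly
    acquired spacers from reads by repeat finding with mismatch tolerance, maps
    them exactly to circular replicons, annotates PAM and strand relative to a
    priming protospacer, ranks unique spacers into hot and cold categories, and
    quantifies motif avoidance (k-mer odds ratios by Fisher's exact test,
    sliding-window AAG profiles with Poisson confidence bounds, regional
    correlations with Fisher z intervals). Includes analysis of
    randomized-trinucleotide prespacer libraries and a seeded simulator of the
    whole experiment (plasmids, prespacer catalogs, acquisition counts, FASTQ
    reads) for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
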