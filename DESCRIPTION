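Package: sgrscreen
Title: Somatic Genetic Rescue Screening from Ultra-Deep Targeted Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection and characterization of low-level somatic mosaicism
    from ultra-deep targeted sequencing of a single locus, as used to screen
    for somatic genetic rescue events in inherited bone marrow failure.
    Provides a duplicate-aware pileup caller with an exact binomial error
    model for variant allele fractions down to 0.25 percent, B-allele
    frequency scanning of constitutional heterozygous SNPs to detect mosaic
    heterozygous deletions and estimate the affected cell fraction,
    soft-clip chimeric-read clustering to localize reciprocal translocation
    breakpoints, exhaustive enumeration of the single-nucleotide variant
    space of a coding sequence with consequence classification, count-based
    dN/dS against the neutral expectation, deleteriousness-score background
    comparison, and cohort-level reporting (mutation spectra, carrier
    fractions, count-versus-age correlation). A synthetic-cohort read
    simulator with truth tables makes every stage testable without access
    to restricted patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
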