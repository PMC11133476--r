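Package: biopanr
Title: Analysis of in Vivo Phage Display Biopanning NGS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for analysing next-generation sequencing data from in
    vivo phage display biopanning screens. Extracts peptide-coding inserts
    from amplicon reads by fuzzy matching of vector flanking sequences,
    applies the library-pattern filtration cascade, clusters peptides by
    WPGMA hierarchical clustering on normalized Hamming distances with
    count-weighted consensus sequences, and implements three hit-selection
    strategies (TOPIC20, TOPIC and SPEC) together with round-over-round
    enrichment analysis. Includes a biopanning simulator that generates
    ground-truthed multi-round, multi-tissue data sets down to error-bearing
    FASTQ reads, so every pipeline stage can be validated against planted
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    jsonlite,
    yaml,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
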