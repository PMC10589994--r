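Package: flankdiv
Title: Reference-Free Detection of Hyper-Diverse Flanking Sequence in
    Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Streams sequencing reads and scans every k-mer ("anchor") for
    statistically hyper-diverse neighbouring k-mers ("targets"), a signature
    of mobile genetic element termini, CRISPR repeats, and cargo-gene
    hotspots. Targets are clustered on the fly by Jaccard similarity over
    7-mer sets; the number of clusters formed per anchor is tested against an
    empirical Poisson-Binomial null with memory-efficient Benjamini-Hochberg
    correction. Includes anchor deduplication, a CRISPR-repeat candidate
    filter, annotation classification from alignment tables, binomial
    regression of target diversity on sample covariates, and a planted-MGE
    read simulator with ROC evaluation so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
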