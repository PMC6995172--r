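Package: teloconv
Title: Bisulfite Conversion Quality Control for WGBS Using Telomeric Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates the bisulfite conversion efficiency of whole-genome
    bisulfite sequencing (WGBS) experiments directly from FASTQ files, using
    the telomeric (CCCTAA)n repeat as a native spike-in control. Telomeric
    C-strand repeats carry three non-CpG cytosines per six-base block; after
    bisulfite treatment the fraction of blocks with 1-3 surviving cytosines
    follows a binomial model in the per-site unconverted ratio (UCR), which is
    recovered by inverting the model on the singly-unconverted block fraction.
    No alignment or reference genome is required. Includes per-site UCRs,
    detection of untreated-DNA contamination from the dispersion of fully
    unconverted blocks, a batch TSV report writer, a synthetic WGBS read
    simulator with a truth ledger, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
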