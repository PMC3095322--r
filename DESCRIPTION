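Package: binmiR
Title: miRNA Target Site Scanning, Curation Scoring and Genetic-BIN/QTL
    Co-Location for Tomato Introgression Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for predicting plant miRNA target sites on transcript
    (unigene) and genomic (BAC) sequences by banded antisense duplex
    alignment, curating candidate sites with a positional mismatch penalty
    score (G:U wobble 0.5, indel 2.0, seed-region mismatch 1.5, other
    mismatch 1.0; minimum over all consecutive 20-nt windows; strict <3
    retention threshold), annotating curated sites against six gene-model
    prediction channels, placing carrier sequences onto the genetic BINs of
    the Solanum pennellii introgression-line map via markers and filtered
    alignments, co-locating sites with fruit metabolic (QML) and
    yield-associated (YAL) loci and expression profiles, and persisting the
    result in a queryable 16-table SQLite store. Includes a seeded synthetic
    fixture generator with machine-readable ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    DBI,
    IRanges,
    RSQLite,
    Rcpp,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
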