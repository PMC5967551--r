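Package: ednapipe
Title: Self-Contained eDNA Metabarcoding Pipeline for Fish 12S Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processes raw paired-end 12S amplicon reads from environmental
    DNA surveys into per-sample species tables with assignment confidence
    scores, neighbor-joining phylogenetic trees, and community diversity
    indices. Every stage is implemented natively: quality trimming of 3'
    tails, overlap-based paired-end merging, N/length filtering, mismatch-
    tolerant primer removal, exact dereplication with count tracking,
    abundance-based denoising, local-alignment taxonomic assignment against
    a user-supplied reference FASTA with identity and e-value cutoffs, a
    log-ratio confidence score for competing species, center-star multiple
    alignment, and canonical neighbor-joining. A simulation module generates
    reference panels and error-bearing read pairs with known community
    composition for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    vegan,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
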