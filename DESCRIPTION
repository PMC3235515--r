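Package: dbcbin
Title: Supervised Compositional Binning of Metagenomic Contigs with de
    Bruijn Chain Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bins assembled metagenomic contigs by sequence composition.
    Each contig is summarized by a de Bruijn chain (DBC) signature: its
    double-stranded k-mer and (k+1)-mer counts define a Markov chain over
    observed k-words, and the chain's stationary distribution, weighted by
    the edge-count mass of each strongly connected component, yields a
    fixed-length signature vector. Named bins are trained from user-supplied
    FASTA sets as centroid signatures, persisted in a plain-text library
    format at word lengths 2-4, and query contigs are assigned to the
    nearest centroid under contig-length and distance cut-offs. Includes
    cross-validation scoring (sensitivity/specificity with a best-two-bins
    rule), a seeded Markov-model metagenome simulator for end-to-end
    testing, and a command-line interface for pipeline use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
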