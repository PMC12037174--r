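Package: plaindex
Title: Error-Bounded Piece-Wise Linear Search Indexes for Sorted K-mer Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds compact search indexes over sorted k-mer lists
    (k-spectra or suffix arrays of genomes).  The rank curve of a sorted
    k-mer list is approximated by a maximal-segment piece-wise linear
    function whose prediction error is bounded by a user-chosen epsilon,
    so search and rank queries only probe a window of 2*epsilon+1 list
    positions.  Segments are found with an online convex-feasibility
    fitter using exact integer arithmetic; breakpoints and segment values
    are stored in succinct encodings (Elias-Fano, delta-from-uniform
    fixed-width, directly addressable codes).  A repeat-stretched variant
    widens fitting ranges by k-mer multiplicity to cut segment counts on
    repetitive genomes, and an exact variant adds a minimal perfect hash
    function plus a per-k-mer error array so rank needs a single list
    probe.  Seeded synthetic genome and list generators make the whole
    package testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    methods,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
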