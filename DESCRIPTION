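Package: sparsemap
Title: Sparsified Minimizer Indexing, Read Mapping and Containment Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Read mapping and alignment-free containment search over
    sparsified genomic sequences. A repeating binary diet pattern excludes
    bases from reference and read sequences before double-strand
    (w,k)-minimizer seeding; the pattern phase of each read is recovered by
    comparing seed occurrence frequencies across the shifted patterns, and
    candidate mapping locations are found by location voting on
    reference-minus-read seed position differences instead of chaining.
    Winning locations are refined by banded affine-gap dynamic programming
    into SAM/PAF records. Also includes a voting-based containment and
    taxonomic profiling mode, a seeding-sensitivity benchmark comparing
    contiguous, minimizer, spaced and sparsified seeds, and a synthetic
    genome/read simulator with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    Biostrings,
    S4Vectors,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
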