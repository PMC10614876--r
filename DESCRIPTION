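Package: prophagr
Title: Prophage Integration Annotation by Homology-Match Defragmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and annotates prophage integrations in bacterial
    genomes from DNA homology matches. Homology hits (HMMER nhmmer tabular
    output, BLAST 12-column tabular output, or the package's built-in
    naive seed-and-extend detector) are filtered by E-value and match
    length, then fragmented alignments arising from diverged or
    interrupted integrations are reassembled into single integration
    calls by colinear chaining under a bounded genome gap and a bounded
    query overlap. Each integration is labelled full length when its
    coverage of the query phage reaches a configurable fraction. Results
    are written as a per-fragment TSV annotation table, BED6 intervals,
    and a JSON summary including per-position occurrence profiles along
    each query phage. A synthetic-genome simulator plants full,
    truncated, and fragmented prophage copies with ground truth so the
    whole pipeline can be exercised and evaluated offline.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
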