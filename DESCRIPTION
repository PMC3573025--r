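Package: transalign
Title: Transitive Sequence Alignments from Pairwise BLAST Hits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Composes pairwise sequence alignments through an intermediate
    sequence database to produce indirect query-to-target ("transitive")
    alignments, scores them by distributing each alignment's bit score
    evenly over its aligned position pairs and taking the minimum under
    composition, and reconciles the possibly inconsistent transitive
    alignments between a query and a target into a single maximum-score
    colinear consensus alignment by dynamic programming. Reads and writes
    BLAST tabular output (outfmt 6 with BTOP traceback or aligned-sequence
    columns), and includes a synthetic tripartite-homology fixture
    generator so the whole pipeline can be exercised without BLAST or any
    sequence database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
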