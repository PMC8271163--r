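Package: cracDecay
Title: Crosslink-Deletion CRAC Target Mapping and SLAM-seq mRNA Decay Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies sequence-specific RNA-binding-protein target
    transcripts from CRAC (cross-linking and analysis of cDNAs) libraries and
    quantifies the consequence of binding on mRNA stability from SLAM-seq time
    courses. Provides crosslink-induced single-nucleotide deletion mapping in
    transcript space, coverage peak calling with a permutation FDR screen,
    expression-normalized target ranking, deletion-centered degenerate motif
    enrichment, first-order decay fitting of T-to-C conversion rates, and
    bound-versus-unbound group comparisons. A seeded synthetic-data generator
    emits transcriptomes, CRAC read libraries, expression tables and SLAM-seq
    count series with planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    zoo,
    Rcpp,
    Biostrings
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse,
    knitr
Config/testthat/edition: 3
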