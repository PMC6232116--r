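Package: priocomm
Title: Consensus Gene Prioritization and Network Communality Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates ranked gene lists from multiple disease-gene
    prioritization methods into a single consensus score, selects a rational
    cutoff from a true-positive/false-positive compromise index, detects
    overlapping k-clique communities in a confidence-filtered protein-protein
    interaction network, weights pathways by the consensus scores of their
    genes and linked communities, clusters communities to nominate the most
    disease-relevant ones, and validates candidate genes against an external
    interaction network (degree-centrality correlation) and a pooled shRNA
    sensitivity screen (RSA-score classification). Ships a synthetic-data
    generator that emulates all pipeline inputs, so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
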