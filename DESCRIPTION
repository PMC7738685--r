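Package: driveways
Title: Overlapping Cancer Driver Module Discovery from Mutations and
    Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies possibly overlapping cancer driver modules in a
    protein-protein interaction network from binary somatic mutation
    profiles. Each candidate module is scored by the product of its sample
    coverage and its mutual exclusivity, and a greedy seed-and-extend
    heuristic assembles a set of connected modules maximizing the summed
    module score under minimum-size and total-size constraints. Includes
    a pseudo-polynomial exact dynamic-programming solver for small
    instances, a seeded synthetic-data generator with planted mutually
    exclusive modules, and a modularity-aware evaluation suite (pairwise
    overlap, hypergeometric enrichment q-values, level-standardized Gene
    Ontology consistency, maximum-weight maximum-cardinality matching,
    best-match precision/recall, and gene-level ROC points).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    fgsea,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
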