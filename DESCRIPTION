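Package: islehaps
Title: Haplotype Networks and Island Colonization Metrics for
    Archipelago Phylogeography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing inter-island colonization histories
    from mitochondrial haplotype data. Collapses aligned sequences into a
    haplotype-by-island frequency table, builds a parsimony haplotype
    network (single-substitution edges with inferred missing
    intermediates), classifies interior and tip haplotypes and ranks them
    by coalescent ancestrality criteria, and computes per-species
    colonization metrics: the chorological minimum, the maximum number of
    potential colonization events, inferred events from haplotype sharing,
    and colonization success. A seeded forward-time island-colonization
    simulator with a ground-truth event log supports end-to-end validation
    of the inference chain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
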