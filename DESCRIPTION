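Package: syntenyTeams
Title: Unordered Gene Clusters, Delta-Synteny Zones and Synteny-Based
    Orthology Refinement in Multiple Genomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects unordered, gap-tolerant, paralog-aware conserved gene
    clusters (delta-clusters, delta-syntenies and delta-zones) across
    multiple genomes from gene-order tables, and uses them to refine an
    existing homologous-family classification into orthologous and
    paralogous subgroups. Implements a sliding-window scan of family-member
    neighbourhoods, witness-coverage merging of clusters into maximal
    syntenies, transitive agglomeration of syntenies into zones, and
    phylogeny-ordered resolution of weak bonds (single shared witness
    genes) into orthologous versus paralogous syntenies. Includes a
    brute-force oracle, a synthetic-genome generator with planted clusters,
    tools to compare two orthologous-group classifications, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
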