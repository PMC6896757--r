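Package: pilesortr
Title: Network-Based Grouping of Pile-Sorted Qualitative Excerpts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for participatory theme elicitation from pile-sort (card
    sort) data. Reads tables of independent pile sorts of qualitative
    excerpts by multiple co-researchers, builds the weighted quote
    co-occurrence network (edge weight = inverse of the number of sorters
    who co-piled a pair), partitions it with two deterministic community
    detection algorithms (divisive edge-betweenness and greedy agglomerative
    modularity maximisation), compares and reconciles the partitions
    (adjusted Rand index, normalised mutual information), renders the
    network diagram with group colours and count-proportional edge widths,
    and writes the per-group quote listings used to seed participatory
    theme discussion. Includes a planted-theme pile-sort simulator for
    validation and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
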