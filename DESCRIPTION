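Package: alibi
Title: Incremental Linearization of Genome Sequence Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Linearizes pangenome sequence graphs (bidirected graphs with
    DNA-labeled nodes and genome path covers) by jointly orienting and
    ordering nodes. Edges are inserted in decreasing weight order into an
    augmented disjoint-set forest that tracks connected components, node
    orientations and positions; within-component conflicts are resolved by
    dynamic topological reordering, so that heavy edges become forward arcs
    and the weighted totals of feedback arcs and reversing joins stay small.
    Includes GFA1 input/output, layout quality metrics (weighted reversing
    join, weighted feedback arc, average cut width) and a structural-variant
    simulator producing pangenome-style graphs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
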