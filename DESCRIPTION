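Package: cherrycount
Title: Counting Cherry Reduction Sequences of Tree-Child Phylogenetic
    Networks via Linear Extensions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for rooted binary phylogenetic networks centred on the
    equivalence between cherry reduction sequences of tree-child networks
    and linear extensions of the reachability poset of internal tree
    nodes.  Provides validation and extended-Newick/edge-list input and
    output for networks, cherry reductions and orchard recognition,
    exhaustive enumeration of reduction sequences, construction of the
    Hasse diagram of the internal-tree-node poset by leaf removal and
    reticulation-edge contraction, exact linear-extension counting
    (brute force, downset dynamic programming, component decomposition
    and a hook-length closed form for forests), reproducible random
    tree-child and orchard network generators, an explicit clique-minor
    network family, graph-minor verification, and level and tree-width
    bound formulas.  Counts are exact arbitrary-precision integers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
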