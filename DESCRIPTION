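Package: streamnet
Title: Memory-Efficient Streaming Simulation of Contact Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Samples undirected contact networks under nine deterministic and
    stochastic graph models (Complete, Path, Barbell, Cycle, Ring Lattice,
    Empty, Erdos-Renyi, Barabasi-Albert, Newman-Watts-Strogatz) as lazy edge
    streams, so that a network is written to disk or piped downstream without
    ever being held in memory.  Includes geometric skip-sampling for sparse
    G(n,p) graphs, an exact integer bijection between flat indices and
    admissible small-world shortcut edges, a tab-delimited edge-list writer
    (plain and FAVITES dialects), a compact fixed-width binary edge format,
    and a command-line front end for epidemic-simulation pipelines.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
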