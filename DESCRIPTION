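Package: eulertigs
Title: Minimum Spectrum-Preserving String Sets Without k-mer Repetitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a minimum-cumulative-length spectrum-preserving string
    set (SPSS) without k-mer repetitions for a set of DNA strings, using an
    arc-centric bidirected de Bruijn graph: the graph is Eulerised by adding
    breaking arcs, a bidirected Eulerian cycle is found with a Hierholzer-style
    search, the cycle is broken at the breaking arcs, and the resulting walks
    are spelled into strings. Also provides the imbalance-based lower bound on
    string count and cumulative length, greedy forward-extension and
    bidirectional-extension heuristics for comparison, unitig compaction, a
    brute-force minimum-SPSS oracle for verification on tiny instances,
    synthetic genome and read generators, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
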