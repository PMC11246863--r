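Package: msps
Title: Maximum-Scoring Path Sets on Vertex-Weighted Graphs of Small Treewidth
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Finds a set of vertex-disjoint simple paths in a vertex-weighted
    directed or undirected graph that maximizes the total vertex weight minus a
    non-negative startup penalty charged once per path (the maximum-scoring
    path sets problem, a graph generalization of maximum-scoring segment sets
    used for sequence segmentation). Provides a linear-time dynamic program for
    path graphs, a dynamic program over the binary decomposition tree of
    two-terminal series-parallel graphs (including graphs built from elastic
    degenerate strings), and a general solver over tree decompositions of
    bounded width with configuration-based bottom-up dynamic programming, plus
    tree-decomposition construction from edge-covering path sets of acyclic
    pangenome graphs, PACE-style graph and decomposition file formats, seeded
    synthetic-instance generators, and an exhaustive oracle for verification on
    small instances.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
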