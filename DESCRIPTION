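Package: dtmsim
Title: Simulation of DNA Alignments Under Discrete-Time Markov Models on
    Phylogenetic Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates DNA multiple sequence alignments evolving under
    discrete-time (nonhomogeneous, possibly nonstationary) Markov models on a
    phylogenetic tree, directly from probability substitution matrices. For
    each edge of an input Newick tree the simulator draws a row-stochastic
    matrix of the requested model class (discrete-time JC69, K80, K81, strand
    symmetric or general Markov) whose log-determinant branch length,
    -1/4 log det(P), equals the edge length exactly, and converts it to
    diagonal-largest-in-column (DLC) form so the generating parameters are
    identifiable from the leaf distribution. A root sequence is then evolved
    site-independently down the tree. Output is a FASTA alignment plus a
    re-parseable parameter file listing the root distribution and every edge
    matrix in a canonical edge order; log-det (paralinear) distance
    diagnostics are included for validating simulated data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
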