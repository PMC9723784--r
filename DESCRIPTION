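Package: lignoplast
Title: Predicting Plastic-Transforming Activity of Lignin-Catabolizing
    Enzymes by Chemical Structural Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict which lignin-catabolizing enzymes encoded in
    bacterial genomes may act on plastic-derived chemical compounds.
    Compounds given as SMILES strings are parsed into molecular graphs,
    fingerprinted (self-contained path and Morgan schemes, plus an optional
    RDKit-backed literature-compatibility backend), and compared with the
    Tanimoto coefficient.  Pairs of plastic-derived (PDCC) and
    lignin-derived (LDCC) compounds at or above a similarity threshold
    (default 65%) form the compound side of an undirected tripartite
    graph whose third partition holds enzymes linked to their LDCC
    substrates; enzyme activities are transferred across similarity edges
    to rank candidate enzymes per plastic compound, annotated with
    per-genome gene counts.  Includes a synthetic compound-family
    benchmark generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: Python with the RDKit library on the PATH (optional;
    only for the 'toolkit_default' fingerprint backend)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
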