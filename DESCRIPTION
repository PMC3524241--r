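Package: psnfold
Title: Fold-Specific Protein Structure Networks and Conserved Interaction Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds side-chain protein structure networks (PSNs) from domain
    coordinates, projects them onto a common multiple-structure alignment as
    length-normalized adjacency matrices (NAMs), and combines an ensemble of
    NAMs into a fold-specific combined adjacency matrix (f-CAM). From the
    ensemble it identifies fold-conserved interactions, spatial structural
    motifs, hubs, node and edge betweenness consensus positions, k=3 cliques
    and clique-percolation communities, and consensus "fold-specific hot
    spots", together with per-column amino-acid propensities and
    Shannon-entropy conservation statistics. Includes a deterministic
    synthetic-fixture generator (toy peptides with engineered side-chain
    contacts and planted alignment ensembles) so every pipeline stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    Matrix,
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
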