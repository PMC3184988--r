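Package: hemenet
Title: Heme-Binding Residue Prediction from Residue Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies heme-binding residues in protein structures by
    representing each chain as a residue interaction network (nodes are
    amino-acid residues, edges are heavy-atom contacts under 5 Angstrom) and
    combining per-structure standardized network centralities (degree,
    closeness, betweenness, clustering coefficient) with sequence
    conservation profiles and surface-geometry descriptors (solvent
    accessibility, atom depth, atom protrusion) in a radial-basis-function
    support vector machine over spatial residue windows. Includes chain-level
    cross-validation, ROC/AUC and Matthews-correlation evaluation,
    feature-characterization statistics (group means, F-scores, t-tests,
    Wilcoxon signed-rank), holo-apo comparison tables, and a synthetic
    structure/network/profile generator with independent brute-force oracles
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
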