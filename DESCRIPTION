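Package: chainknot
Title: Deterministic Smoothing and Knot Detection for Open Biopolymer Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Topology-preserving simplification of open 3D polymer chains
    (protein, RNA or chromatin backbones) by deterministic, triangle-guarded
    bead smoothing, together with knot classification of the reduced chain.
    The reduced chain is projected to a generic plane, its crossings encoded
    as a Dowker-Thistlethwaite code under implicit closure, simplified by
    Reidemeister-move calculus and named in Alexander-Briggs notation.
    Includes slipknot subchain analysis, composite-knot factoring,
    inter-chain link detection, PDB/mmCIF/XYZ input, trajectory output in
    multi-MODEL PDB, parametric ground-truth fixture generators, and a
    command line tool.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
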