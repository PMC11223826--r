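Package: IfaceTess
Title: Tessellation-Derived Macromolecular Interfaces, Binding Sites and
    Non-Redundant Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives interatomic and residue-residue contact surface areas
    from macromolecular assemblies by a power (Laguerre) tessellation of
    solvent-expanded atomic balls, extracts typed protein-protein,
    protein-peptide and protein-nucleic acid interfaces and binding sites,
    annotates inter-chain hydrogen bonds, salt bridges and disulfides, and
    reduces redundancy by combined sequence clustering and contact-area
    similarity (CAD-score variants) with Taylor-Butina clustering at three
    stringency levels. Includes a deterministic generator of idealized toy
    assemblies so the whole pipeline is testable without external data, and
    a command-line interface over the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
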