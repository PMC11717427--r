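Package: genetriage
Title: Gene-List Meta-Analysis and Predicted-Dimer Interaction Triage
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for prioritizing genes across heterogeneous collections of
    published gene lists and for triaging predicted protein-dimer structures
    into interaction calls. Implements frequency- and selectivity-weighted
    regulation scores, co-occurrence analysis via Jaccard distance and
    symmetric normalized mutual information with Girvan-Newman community
    detection, hypergeometric overlap simulations, PAE- and distance-based
    inter-chain residue constraint calling with buried-interface-area
    normalization, model-convergence RMSD analysis, six-frame reading-frame
    scans, and seeded synthetic-data generators so the whole pipeline is
    testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    ape,
    Biostrings,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
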