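Package: packnet
Title: Side-Chain Packing Topology in Protein Interiors via Surface
    Contact Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds residue interaction networks inside single protein
    chains from van der Waals surface complementarity (Sm) and overlap
    (Ov) between side-chain surfaces, and from inter-atomic distances.
    Provides dot-sampled van der Waals surface generation, solvent
    accessibility and burial ratios, weighted contact-network statistics
    (degree, strength, clustering, maximal cliques, random-graph nulls),
    canonical identification and family classification of recurring
    packing motifs, geometric characterisation of three-residue cliques
    (inter-origin triangles, tilt and swivel angles, chi-squared tests
    against the analytic sine null), and fold-compatibility scoring of
    candidate structures against conserved-link fold signatures (snet,
    dnet). Includes deterministic synthetic generators (surface patch
    pairs, random graphs, triplet frames, toy all-atom structures) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
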