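Package: orthonet
Title: Query-Centred Interactome Construction by Interolog Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a human-projected protein-protein interaction network for
    an arbitrary query protein list from per-species interaction tables.
    Species networks are cleaned (physical-only, intra-species, identifier
    normalisation), queried for first neighbours, projected onto human genes
    through ortholog groups (interologs), filtered against known human
    interactions, and merged into a single interactome with per-edge
    provenance.  The merged network is characterised by six graph measures
    against a random-query null model, and its members are mined for
    over-represented GO terms which are assembled into a functional map.
    A deterministic multi-species fixture generator with planted ground truth
    makes every pipeline stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    xml2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
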