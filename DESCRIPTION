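Package: zipmech
Title: Conformational Landscapes and Elevator-Mechanism Analysis of ZIP
    Metal Transporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse structure ensembles of ZIP (SLC39) family
    metal transporters: rigid-body superposition and principal component
    analysis of alpha-carbon coordinates to extract inward- and
    outward-facing conformers, quantification of the elevator-type
    transport mechanism (transport/scaffold domain decomposition,
    membrane-axis displacement of the metal-binding sites, hydrophobic
    plug contact-state classification), and projection of reference
    BbZIP anchor residues through a multiple sequence alignment to
    annotate binuclear-metal-center motifs, gating residues and
    hydrophobic plugs across the fourteen human ZIPs. Includes a
    ground-truthed synthetic generator of two-domain helical-bundle
    transition ensembles and motif-planted alignments so the whole
    pipeline is testable without structure prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
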