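Package: secretominer
Title: Comparative Mining of Fungal Secretomes and Small Secreted Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts classically secreted proteins from per-protein
    localization evidence (signal peptide, transmembrane topology,
    subcellular targeting, C-terminal ER-retention motifs), annotates the
    resulting secretomes into functional categories (CAZymes, proteases
    with an endo/exo split, GX/GGGX lipases, small secreted proteins),
    clusters small secreted proteins by global sequence identity with a
    greedy incremental algorithm, partitions clusters by fungal lifestyle
    to separate shared from lifestyle-specific protein families, and
    provides enrichment and group-comparison statistics. A seed-controlled
    synthetic proteome generator with planted ground truth supports fully
    self-contained benchmarking of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
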