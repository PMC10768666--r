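Package: holometab
Title: Comparative Host-Endophyte Metabolomics by Feature-Based Molecular
    Networking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for comparing the metabolome of a plant
    host with that of its cultured fungal endophyte community from
    untargeted LC-MS/MS data. Covers feature-table post-processing
    (duplicate removal, isotope grouping, join alignment, blank
    subtraction, replicate-based detection calls, normalization),
    feature-based molecular networking with modified-cosine spectral
    similarity (mutual top-K edge pruning and molecular-family size
    capping), taxonomically informed metabolite annotation with
    network-consensus chemical-class assignment, and host-versus-fungal
    overlap statistics (shared features, shared molecular families,
    per-strain overlap, fractionation enrichment, class distributions).
    A seeded synthetic-data module emulates the full study design
    (strain extracts, chromatographic fractions, blanks, replicates)
    with ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
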