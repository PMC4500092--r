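Package: jointscape
Title: Epistasis and Accessible Evolution in Joint Protein-DNA Sequence Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting combinatorially complete transcription
    factor x response element binding-energy landscapes. Implements the
    abc/WYK tetrahedral encoding of protein and nucleotide states, nested
    ordinary-least-squares epistasis models through third order (within the
    protein, within the DNA, and across the molecular interface), extraction
    of state-level main and epistatic effects with variance partitioning and
    likelihood-ratio significance, numeric energy logos, single-site binding
    curve fitting from fluorescence-anisotropy titrations, functional-complex
    classification, neutral-network construction and evolutionary-pathway
    accessibility analysis (including permissive and restrictive gating
    across the interface), structural-feature correlation, and a seeded
    synthetic landscape generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
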