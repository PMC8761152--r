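Package: memqa
Title: Quality Assessment of Predicted Transmembrane Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing predicted alpha-helical membrane protein
    structures at proteome scale: per-region pLDDT confidence summaries, a
    hydrophobic-thickness statistic computed from topology-annotated C-alpha
    geometry with a physiological-band error flag, optimal rigid
    superposition (Kabsch), TM-score with the iterative fragment-seeded
    search, GDT_TS, a sequence-independent structural aligner, fold
    classification against a reference library, and a PFAM/hmmsearch-based
    target selection filter.  Includes a synthetic helix-bundle generator
    with known ground truth so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
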