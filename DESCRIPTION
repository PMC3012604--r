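Package: immfam
Title: Classification of Plant Immunophilin (FKBP and Cyclophilin) Families
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequence-based classification of immunophilins, the FK506-binding
    proteins (FKBPs) and cyclophilins (CYPs) that share peptidyl-prolyl
    cis/trans isomerase (PPIase) activity. Detects PPIase domain copies by
    iterative local alignment against the human FKBP12 and cyclophilin A
    reference domains, scores conservation of the key drug-binding/catalytic
    residues at the fixed reference positions, applies heuristics for
    twin-arginine (Tat) thylakoid-lumen targeting signals, ER retention
    motifs and nuclear localization signals, derives ortholog-based gene
    names with molecular-weight fallback suffixes, and builds
    neighbor-joining family trees from progressive multiple alignments.
    Ships the transcribed rice/Arabidopsis key-residue conservation tables
    as fixtures, a ditto-notation table parser/renderer with a recomputation
    audit, and a seeded generator of immunophilin-like synthetic protein
    families with machine-readable ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
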