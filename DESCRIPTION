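Package: smydfam
Title: Phylogenetic Classification of the Smyd Gene Family
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying SET-and-MYND-domain (Smyd) protein
    sequences into their major metazoan classes (Smyd3, Smyd4 with its
    Smyd4/Smyd4L/Smyd4I groups, Smyd5, the arthropod-specific SmydA and the
    atypical TPR-Smyd group). Provides homology-filter logic for BLAST
    tabular output, detection and categorization of degenerate MYND-type
    cross-brace zinc fingers against a bundled signature, reference-anchored
    extraction of the interrupted SET-MYND core from multiple alignments,
    gamma-corrected protein distances with deterministic neighbor-joining
    and bootstrap clade support, domain-architecture assembly, combined
    tree-plus-architecture class assignment, and a synthetic Smyd-family
    generator with full ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    seqinr,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
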