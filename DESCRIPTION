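Package: itamorigins
Title: Degenerate ITAM Screening, Molecular-Clock Dating, and
    Phagocytosis Biophysics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational pipeline around receptor-independent
    phagocytosis signaling: proteome-wide scanning for the degenerate
    two-half-site ITAM probe Y-x-x-(L/I)-x(6-12)-Y-x-x-(L/I) with
    expression-based candidate ranking and rule-based exclusion;
    amino-acid distance and neighbor-joining phylogenetics with
    bootstrap supports, divergence-time calibration, per-branch
    substitution-rate profiles, and per-clade molecular-clock root
    dating of paralog duplications; fluorescence quantification
    operators (line profiles, kymographs, contact/reference
    normalized fluorescence, pattern fold change, generalized
    polarization); Hertz-model Young's-modulus estimation from
    force-indentation curves and an exact-permutation Spearman test
    for stiffness-uptake correlation. Ships synthetic-data generators
    with known ground truth for every input class so all stages are
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
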