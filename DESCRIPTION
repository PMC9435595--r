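Package: mxbuild
Title: Automated Macromolecular Model-Building Pipeline Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-usable building blocks of an automated crystallographic
    model-building pipeline: domain types and readers/writers for
    macromolecular models (PDB/mmCIF), reflection data (structure-factor
    mmCIF) and electron-density maps (CCP4/MRC); space-group operator
    algebra with origin-shift enumeration; density peak picking with
    dummy-atom flooding and water placement; per-residue score-driven
    pruning and rebuild selection; evaluation metrics (symmetry- and
    origin-aware model completeness, F-map correlation, R factors,
    quality gates); and an R_free-gated cycle state machine with
    pluggable building/refinement backends plus scripted and toy
    backends and synthetic fixture generators so the whole pipeline is
    testable without external programs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
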