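Package: aprvote
Title: Consensus Prediction of Aggregation-Prone Regions in Protein Sequences
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects amyloidogenic determinants ('aggregation-prone' regions,
    APRs) in protein sequences by combining eleven component predictors under a
    per-residue majority vote: five methods run natively from packaged
    propensity scales, a hexapeptide sequence pattern and a position-specific
    scoring matrix, and six are consumed as externally computed per-residue
    score tables through threshold adapters. A residue is a consensus hit when
    at least floor(n/2) of the n participating methods flag it. Includes the
    per-residue benchmark protocol (sensitivity, specificity, Q, Matthews
    correlation coefficient, macro-averaged MCC), DSSP-based surface-exposure
    classification of predicted peptides, a substitution-scan mode for
    solubility engineering, a deterministic synthetic-fixture generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
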