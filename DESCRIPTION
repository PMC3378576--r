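Package: strucClass
Title: Protein Structural Class Prediction from PSSM Profiles via
    Iterative Multiple Linear Regression
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the SCOP structural class (all-alpha, all-beta,
    alpha/beta, alpha+beta) of a protein domain from the PSI-BLAST
    position-specific scoring matrix (PSSM) of its sequence. A
    440-dimensional sequence feature vector is extracted from the PSSM and
    mapped by a two-round iterative least-squares multiple linear
    regression onto a 4-dimensional structural feature vector whose signs
    determine the class. Includes sliding-window secondary-structure
    composition targets, sequential forward stepwise feature selection,
    confusion-matrix metrics (sensitivity, specificity, Matthews
    correlation, generalized squared correlation), cross-validation and
    jackknife harnesses, readers and writers for FASTA and ASCII PSSM
    profiles, and a synthetic domain generator so the full pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
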