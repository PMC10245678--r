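Package: densid
Title: Profile HMM Protein Identification and Model Validation for
    Cryo-EM Model Building
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns per-residue amino-acid probability profiles and
    confidence scores, as emitted by automated cryo-EM model-building
    programs, into profile hidden Markov models for protein
    identification against a proteome. Profiles are serialized to the
    HMMER3 text format and searched with an internal Forward/Viterbi
    engine with Gumbel E-value calibration. Includes the model
    post-processing rules used after identification (mutation of
    matched residues, chain connection, pruning of short chains, and a
    backbone-RMSD based confidence score stored in the B-factor
    column), a validation metric suite (C-alpha and backbone RMSD,
    recall, precision, amino-acid accuracy, completeness, Q-score and
    Fourier shell correlation), and a synthetic-data generator so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    S4Vectors,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
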