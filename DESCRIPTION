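Package: skipAO
Title: Target-Site Screening and Efficacy Prediction for Exon-Skipping
    Antisense Oligonucleotides
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes target-site descriptors for splice-switching antisense
    oligonucleotides at every position of an exon (duplex and flanked-region
    binding free energies, target-site accessibility, splice-acceptor distance,
    hexamer neighborhood-inference scores, exon/intron GC architecture),
    applies published least-squares and ordinal-logistic formulas to predict
    exon-skipping efficacy for phosphorodiamidate morpholino (PMO) and
    2'-O-methyl chemistries, and provides the model-derivation machinery
    (stepwise forward selection with K-fold cross-validation, centered
    interactions, confusion matrices, leave-one-exon-out refits) to refit the
    models on compiled oligo-efficacy datasets. Ships a simplified
    nearest-neighbor folding engine with an exhaustive-enumeration oracle for
    testing, and an adapter to the ViennaRNA command-line tools for production
    energy and accessibility calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    MASS,
    zoo,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
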