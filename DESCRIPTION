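Package: barcodeaudit
Title: COI DNA-Barcode Species Identification and Seafood Mislabeling Audits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying seafood samples from cytochrome oxidase I
    (COI) barcode sequences and auditing menu listings for mislabeling.
    Implements codon-aware alignment with nuclear-pseudogene (numt) screening,
    percent-identity searches against local reference panels, maximum-likelihood
    phylogenetics under GTR-family models with discrete-Gamma rate heterogeneity
    and codon-position partitioning (BIC model selection, NNI search,
    nonparametric bootstrap), Bayesian tree MCMC with monophyly constraints,
    stepping-stone marginal-likelihood estimation and Bayes-factor topology
    tests, a diagnostic nucleotide character key for tunas, and a rule-based
    menu-listing adjudication report. Seeded simulators for codon-structured
    COI-like data and mislabeling scenarios support end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    coda,
    jsonlite,
    phangorn,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
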