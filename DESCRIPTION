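Package: rshkit
Title: Classification and Divergence Analysis of RelA/SpoT Homolog Protein Superfamilies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying members of the RelA/SpoT homolog (RSH)
    protein superfamily into subfamilies and for analysing their functional
    divergence. Provides profile hidden Markov models with Gumbel E-value
    calibration for domain discovery, iterative subgroup refinement driven by
    neighbor-joining phylogenies with bootstrap support, domain-architecture
    nomenclature and genome-complement rules, consensus-based differential
    conservation analysis, clade-versus-clade type I/II functional-divergence
    statistics, and a synthetic protein-superfamily simulator with known truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
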