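Package: crusim
Title: Stochastic Calcium-Release-Unit Simulation of Ventricular Myocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Local-control stochastic simulation of cardiac
    excitation-contraction coupling in a guinea-pig-like ventricular
    myocyte.  Thousands of calcium release units -- dyadic subspaces
    coupling Markov-gated L-type channel and RyR2 clusters to junctional
    sarcoplasmic reticulum compartments -- drive a Luo-Rudy-style action
    potential.  Includes a scenario system for calsequestrin-null (CPVT2)
    and beta-adrenergic parameter changes, constant and slow-rapid-slow
    pacing protocols, and arrhythmia analytics: action potential duration,
    calcium transients, spark counting, alternans, early
    afterdepolarizations and skipped-beat detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
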