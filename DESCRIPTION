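Package: iimfit
Title: Maximum-Likelihood Inference Under the Isolation-with-Initial-Migration Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast maximum-likelihood fitting of two-deme speciation models to
    pairwise segregating-site counts at many independent loci. Implements the
    isolation-with-initial-migration (IIM) coalescent with asymmetric gene flow
    and unequal population sizes: closed-form densities of pairwise coalescence
    times via eigen-decomposition of the migration-stage generator, stable
    evaluation of the segregating-sites probability mass function, multilocus
    likelihood maximisation in a mutation-scaled parameterisation, nested model
    selection by likelihood-ratio tests (including parameter-on-the-boundary
    cases), Wald and profile-likelihood confidence intervals, conversion of
    estimates to demographic units, composite-likelihood (Godambe) robust
    standard errors and robust likelihood-ratio tests for linked loci, and a
    matching coalescent simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    Rcpp,
    utils,
    lhs,
    jsonlite,
    optparse
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
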