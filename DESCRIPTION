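Package: jacquardcls
Title: Constrained Least-Squares Estimation of Jacquard Genetic Identity Coefficients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of the nine condensed Jacquard genetic identity
    coefficients for pairs of individuals from bi-allelic genotype data by
    constrained least squares on the probability simplex, together with the
    relatedness parameters that derive from them (kinship/coancestry,
    inbreeding, theta3, theta4, relative coancestry and inbreeding, and
    allele-sharing estimators). Includes exact solvers for the consistent
    bi-allelic condensed system with the (xi, eta) parametrization of the
    non-identified solution set, a pedigree gene-dropping simulator that
    produces realized ("gold") identity coefficients from labelled founder
    alleles, and an RMSE benchmark harness comparing estimates against the
    gold values under different allele-frequency sources and minor allele
    frequency filters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
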