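Package: gdtpoly
Title: Within-Family Association Tests for Polytomous Phenotypes and
    Two-Locus Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Score tests of genetic association for phenotypes with K >= 2
    unordered categories in extended pedigrees, generalizing the
    Generalized Disequilibrium Test (GDT) built from phenotype-discordant
    relative pairs.  Supports models with markers at two unlinked loci,
    including conditional tests of one locus given an established risk
    locus and gene-gene interaction coefficients, with variance estimates
    using identity-by-descent sharing or kinship coefficients.  Includes a
    Merlin/QTDT pedigree file interface, a gene-dropping pedigree
    simulator with a polygenic liability component and family
    ascertainment, comparator tests (dichotomous GDT variants and
    GEE-based Wald tests), and a Type-I-error / power evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    nnet,
    sandwich,
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
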