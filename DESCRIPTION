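Package: nrvat
Title: Copula-Based Rare-Variant Set Association Tests for Binary Traits in Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Region-based association testing between a set of rare or common
    genetic variants and a binary trait in family-based designs. The test couples
    a marginal logistic regression model with a Gaussian copula whose correlation
    within each family is h2 * Psi + (1 - h2) * I, where Psi is twice the kinship
    matrix and h2 the polygenic heritability, estimated by pairwise composite
    likelihood. A variance-component score statistic Q = (Y - mu)' K (Y - mu) is
    referred to its mixture-of-chi-square null distribution with a sandwich
    residual covariance. Includes linear, quadratic, IBS, Gaussian and polynomial
    kernels, pedigree kinship computation, PED/FAM and dosage I/O, and a
    simulation engine for linked-SNP genotypes (founder haplotypes with
    calibrated adjacent-SNP linkage disequilibrium, Mendelian gene dropping) and
    binary phenotypes under Gaussian-copula, GLMM, Student-t-copula and
    chi-square-copula familial dependence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    yaml
Config/testthat/edition: 3
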