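Package: admixls
Title: Least-Squares Inference of Population Structure from Genotypes
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimates ancestral population allele frequencies (P) and
    individual admixture proportions (Q) from a matrix of biallelic SNP
    genotypes by a least-squares approximation to the binomial admixture
    likelihood.  The fit alternates a bounded-variable least-squares update
    for the allele frequencies with a simplex-constrained least-squares
    update for the admixture proportions, optionally penalized by a
    symmetric Dirichlet degree-of-admixture prior.  Also provides
    closed-form variance bounds for the partially-solved estimators, a
    binomial genotype simulator, evaluation harnesses (population
    alignment, RMSE, factorial simulation studies), readers and writers for
    plain-matrix and vcftools "012" genotype files and ADMIXTURE-style
    .P/.Q outputs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
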