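Package: micropig
Title: Microbiability and Heritability Estimation with Bayesian Kernel Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the proportions of phenotypic variance explained by the
    gut microbiota (microbiability) and by host genetics (heritability) for
    quantitative traits, using Bayesian reproducing kernel Hilbert space (RKHS)
    mixed models fitted by Gibbs sampling. Builds microbial covariance matrices
    from log-transformed, standardized OTU abundances and genomic relationship
    matrices by VanRaden's first method; supports rarefaction, OTU
    prevalence/abundance filtering and SNP quality control; fits single- and
    two-kernel models with BIC comparison, breeding-value re-ranking analysis,
    and main-plus-diet-specific variance decompositions for genotype-by-diet
    and microbiota-by-diet interactions. Includes a synthetic-data generator
    emulating full-sib designs split across two diets, with known
    variance-component truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    biomformat,
    yaml,
    jsonlite
Config/testthat/edition: 3
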