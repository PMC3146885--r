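Package: admixkit
Title: Maximum-Likelihood and Penalized Estimation of Individual Ancestry
    from SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates individual ancestry fractions and ancestral population
    allele frequencies from diploid biallelic SNP genotype matrices under the
    binomial admixture model. Fits by block relaxation with sequential
    quadratic programming and safeguarded quasi-Newton extrapolation, supports
    v-fold entry-masking cross-validation for choosing the number of ancestral
    populations or the penalty strength, a supervised mode that fixes the
    ancestry of labeled reference individuals, and an approximate-L0 penalty
    that drives small admixture coefficients to zero. Includes a
    Balding-Nichols simulator and evaluation statistics (frequency RMSE, FST
    estimates, ancestry bias curves), plus readers and writers for PLINK
    binary genotypes and Q/P estimate files.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
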