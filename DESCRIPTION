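Package: stratimpute
Title: Stratified Genotype Imputation with Cluster-Guided Haplotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genotype imputation for structured populations. Individuals are
    partitioned into genetic subgroups by silhouette-guided K-means on the
    numeric genotype matrix, each subgroup is imputed independently with a
    Li-Stephens-style haplotype-copying hidden Markov model, and the results
    are merged back in the original taxa order. Includes adapters between
    numeric (0/1/2/NA), HapMap and VCF genotype formats, a synthetic
    structured-population simulator with masking for benchmarking, an
    imputation matching-rate harness, and a downstream evaluation suite
    (QTN phenotype simulation, single-marker GWAS with power/FDR/Type-I
    accounting, GBLUP heritability estimation by REML and k-fold
    cross-validated genomic prediction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    parallel,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
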