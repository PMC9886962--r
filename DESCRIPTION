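Package: grazescan
Title: Population Structure and Genotype-Environment Association Scans for
    Forage Landscape Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landscape-genomics analysis of perennial forage
    populations sampled along environmental gradients: maximum-likelihood
    admixture inference with Evanno delta-K model selection and run
    alignment, Nei genetic distances with UPGMA trees and locus bootstrap,
    discriminant analysis of principal components, a redundancy-analysis
    (RDA) genome scan with robust Mahalanobis outlier detection and
    genomic-inflation-corrected q-values, linkage-disequilibrium decay
    summaries, growing-degree-day phenology, Tukey HSD mean separation and
    ancestry-phenotype regression. A synthetic-data generator with known
    ground truth supports parameter-recovery validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    ape,
    vcfR,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
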