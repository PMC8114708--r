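Package: ascbias
Title: Simulation and Imputation-Based Mitigation of SNP Ascertainment Bias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the non-random discovery of SNPs for genotyping
    arrays distorts allele-frequency based population genetic estimators, and how
    far genotype imputation against a small sequenced reference panel corrects the
    distortion. Provides a multi-population genotype simulator with known truth
    (Balding-Nichols differentiation, founder-mosaic linkage disequilibrium,
    pooled-sequencing read noise), in-silico array design by discovery-population
    minor allele frequency filtering, five reference-panel sampling strategies, a
    Li-Stephens haplotype-copying hidden Markov model imputer with per-site dosage
    r-squared, estimators of expected and observed heterozygosity, Nei's standard
    genetic distance and ratio-of-sums F_ST, and group-specific regression
    diagnostics of bias with leave-one-out imputation validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
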