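Package: aeqtlmap
Title: Allelic and Total Expression QTL Mapping with Phase-Uncertainty
    Mixture Likelihoods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps cis-acting regulatory variation by combining allelic
    expression ratios measured at multiple transcribed SNPs per gene in a
    lognormal likelihood whose genotype-dependent means mix over the
    posterior distribution of haplotype phase, estimated by an EM algorithm
    under Hardy-Weinberg equilibrium.  Includes the companion total-expression
    (eQTL) regression arm with covariate adjustment and outlier screening,
    genomic-DNA normalization of allelic ratios, delta-Ct quantification of
    total expression, genotype quality control, Bonferroni family-wise error
    rates, linkage-disequilibrium statistics, cis-variance decomposition,
    cross-scan comparisons, and a two-cohort synthetic-data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
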