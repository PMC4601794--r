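Package: ImputeAccuracy
Title: Genotype Imputation Accuracy Assessment with Chance-Corrected Agreement
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes per-SNP genotype imputation accuracy statistics from
    imputed genotype probabilities and withheld true genotypes: concordance
    rate, chance agreement, the Imputation Quality Score (a Cohen's-kappa-style
    chance-corrected agreement statistic on the imputed-versus-actual
    probability contingency table), squared dosage correlation, the allelic
    R-squared reported by BEAGLE, and the IMPUTE2 INFO measure. Provides a
    masking workflow that hides genotypes at SNP-array positions (or a random
    fraction of markers) so imputed output can be scored against withheld
    truth, minor-allele-frequency and linkage-disequilibrium (EM haplotype
    r-squared) annotation, 0.01-increment bin summaries, readers for VCF,
    IMPUTE2 .gen and BEAGLE .gprobs probability dialects, and a seeded
    synthetic-data generator that emulates the masking experiment at desk
    scale, including a chance-level major-homozygote imputer that reproduces
    the inflation of concordance rate at rare variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
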