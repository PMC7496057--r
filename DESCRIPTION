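Package: breedgwas
Title: Across-Breed Genetic Association with Breed-Level Traits in Pedigree Dogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An across-breed association pipeline for breed-level quantitative
    traits in pedigree dogs: simulation of breed-structured genotype/phenotype
    cohorts (Balding-Nichols allele-frequency divergence), PLINK text
    genotype input/output, the standard quality-control cascade (per-breed
    sample capping, missingness, minor allele frequency, Hardy-Weinberg exact
    test, linkage-disequilibrium pruning), candidate-SNP extraction around
    gene sets, trait residualization and jackknifed Spearman correlation, a
    per-SNP additive-model association scan with a breed-randomised min-P
    (max-T) permutation family-wise correction, and resampling and
    allele-frequency-correlation robustness checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
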