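Package: longevar
Title: Pooled-Sequencing Candidate-Gene Association Analysis for Longevity Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for candidate-gene association studies of human longevity
    based on pooled target-capture sequencing of centenarian cases and
    younger controls. Provides a synthetic cohort generator with a
    pooled-read sampling model, minor-allele adjusted allele-frequency
    estimation, single-variant Fisher exact association with multiplicity
    correction and rarity/enrichment partitioning, gene-based
    variance-component tests (rare-variant kernel, combined common+rare,
    and optimal directional combination) with moment-matched and seeded
    permutation p-values, rule-based amino-acid substitution classification
    (conservative/non-conservative/radical), a six-criterion variant
    prioritization cascade with hotspot-gene detection, and permutation
    gene-set enrichment of age-related-disease categories against
    configurable backgrounds.
License: MIT
Encoding: UTF-8
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
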