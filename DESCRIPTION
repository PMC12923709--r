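Package: priogwas
Title: Gene Prioritization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A locus-to-gene prioritization pipeline for genome-wide
    association study (GWAS) summary statistics. Starting from per-variant
    association records and a linkage-disequilibrium (LD) reference panel,
    the package performs variant quality control, greedy LD clumping,
    stepwise conditional-joint selection of independent signals,
    single-causal approximate-Bayes-factor fine-mapping with credible sets,
    LD-aware gene-based association tests, feature-based gene priority
    scores fitted by leave-one-chromosome-out ridge regression, rule-based
    gene prioritization (priority-score plus nearest-gene, non-synonymous
    fine-mapped variants, rare-variant burden evidence), enrichment tests,
    two-trait colocalization posteriors, and drug-target tier annotation.
    A seeded synthetic-data generator produces block-LD reference panels,
    summary statistics, gene models, gene features, and truth tables for
    calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
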