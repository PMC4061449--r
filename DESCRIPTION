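Package: wgaqc
Title: Quality Control for Whole-Genome-Amplified Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coverage quality control for whole genome amplification (WGA)
    experiments such as multiple displacement amplification (MDA). Bins
    per-base depth tracks, computes breadth of coverage and two-sample
    balance statistics (per-bin fold variation and log2 ratios), builds
    Lorenz curves and Gini coefficients of coverage evenness with binomial
    depth matching, classifies metagenomic BLAST tabular hits by weighted
    per-read voting with clade collapsing, and performs qPCR standard-curve
    quantitation with limit-of-detection censoring and decontamination
    fold-reduction bounds. Includes a seeded synthetic-data generator
    (lognormal-Poisson amplification bias, mixed-species hit tables, qPCR
    dilution series) so every stage can be validated against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
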