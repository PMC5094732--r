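Package: npcombine
Title: Non-Parametric Combination of Permutation Tests for Multi-Omics Integration
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Non-Parametric Combination (NPC) framework for the
    integrative analysis of heterogeneous omics datasets measured on the same or
    partially overlapping samples. Each data modality (sequencing counts,
    microarray-like continuous values, ordinal genotypes, or generic numeric
    features) is analysed with a modality-appropriate association statistic;
    synchronized sample permutations preserve between-dataset correlations, and
    partial permutation p-values are combined across modalities with the Fisher,
    Liptak or Tippett functions into a single global p-value per feature.
    Comparison methods (parametric Fisher p-value combination, rank-sum and
    rank-product meta-analysis and their NPC-wrapped variants, and the
    Benjamini-Heller partial-conjunction test), calibration diagnostics based on
    the joint null criterion (double Kolmogorov-Smirnov test), partial-AUC
    performance evaluation, and data simulators for benchmarking are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: StatisticalMethod, MultipleComparison, GeneExpression, Epigenetics
RoxygenNote: 7.3.3
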