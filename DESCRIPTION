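Package: mrmqc
Title: Analytical and Clinical Validation of Scheduled-MRM Plasma Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for validating single-injection,
    scheduled multiple-reaction-monitoring (MRM) plasma metabolomic methods.
    Covers the full validation workflow: transition-library handling and
    acquisition scheduling (detection windows, concurrency profiling,
    dwell-time budgeting with polarity-switching overhead), in-silico
    chromatogram acquisition and peak-quality metrics with lognormal
    summaries, balanced-precision variance components (intra-, inter- and
    total CV), admixture linearity, carryover assessment, blood-collection-tube
    and inter-instrument concordance analyses, and a case/control biomarker
    workflow (NIPALS PLS-DA, random-forest panel selection, AUROC with
    bootstrap confidence intervals, repeated double cross-validation and
    permutation testing). A synthetic-data module generates transition
    libraries and study-design peak-area matrices with realistic variance
    structure so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mixOmics,
    pROC,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
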