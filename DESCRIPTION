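Package: filterFDR
Title: Effects of Feature Filtering on FDR Control and Power
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies and detects the bias that feature filtering (signal,
    fold-change and variance filters) induces on false discovery rate
    estimation in two-group differential expression analysis. Implements
    per-feature filter statistics, FDR procedures expressed through the
    empirical cdf of the p-values (Benjamini-Hochberg, Benjamini-Yekutieli,
    adaptive BH, q-value, Bonferroni), exact post-filter distribution theory
    for the pooled two-sample t statistic, a permutation-based statistical
    test for filtering-induced FDR bias, and a simulation engine measuring
    achieved FDR, observed power and the retained null proportion as a
    function of the fraction of features filtered out.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: MultipleComparison, DifferentialExpression, StatisticalMethod,
    GeneExpression
RoxygenNote: 7.3.3
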