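Package: mrbiome
Title: Bidirectional Two-Sample Mendelian Randomization for Microbiome
    and Addiction GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization
    between a behavioural trait (nicotine dependence) and gut-microbiota
    abundance measured at five taxonomic levels.  Covers instrument
    selection (p-value and minor-allele-frequency filters, greedy LD
    clumping, F-statistic strength screening, Steiger directionality
    filtering), exposure-outcome harmonization of GWAS summary
    statistics, five univariable causal estimators (inverse-variance
    weighted, MR-Egger, weighted median, simple and weighted mode), a
    sensitivity suite (Cochran's Q, Egger intercept, leave-one-out,
    funnel data, MR-PRESSO), multivariable MR with conditional
    instrument-strength statistics, a many-taxa screening pipeline with
    per-level Bonferroni correction, and a synthetic GWAS
    summary-statistic generator with known ground truth so the whole
    workflow is testable without access to the original cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
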