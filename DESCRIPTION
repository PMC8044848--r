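Package: bidirMR
Title: Bidirectional Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization on
    GWAS summary statistics: instrument selection and quality control
    (significance, minor-allele-frequency and Hardy-Weinberg filters,
    palindrome exclusion, greedy linkage-disequilibrium clumping, proxy
    lookup, variance explained and F-statistics), allele harmonization
    across studies, causal estimation (Wald ratio, fixed- and
    multiplicative-random-effect inverse-variance weighting, MR-Egger
    regression with intercept test, weighted median with bootstrap
    standard errors, MR-PRESSO global/outlier/distortion tests),
    heterogeneity and pleiotropy diagnostics (Cochran's Q, leave-one-out,
    funnel data), binary-outcome power analysis, and a summary-level
    simulator with known ground truth for calibration and testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), metafor, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
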