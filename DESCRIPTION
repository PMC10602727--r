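Package: microMR
Title: Bidirectional Two-Sample Mendelian Randomization for Microbiome Exposures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for bidirectional two-sample Mendelian randomization (MR)
    with many exposures, as used to screen gut-microbiome taxa against a
    disease outcome. Covers instrument selection (p-value threshold, greedy
    LD clumping, confounder exclusion, F-statistic filtering), allele
    harmonization with palindromic-variant removal, five causal estimators
    (inverse-variance weighted, MR-Egger, weighted median, simple and
    weighted mode), pleiotropy and heterogeneity diagnostics (MR-PRESSO
    global/outlier/distortion tests with sequential outlier removal,
    Egger intercept, Cochran's Q, leave-one-out), rank-level Bonferroni
    thresholds, reverse-direction analysis, and a synthetic summary-statistics
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
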