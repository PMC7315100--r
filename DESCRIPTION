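Package: rmaov
Title: N-Way Repeated-Measures ANOVA via Effect Coding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Effect-coding based repeated-measures ANOVA for factorial
    within-subject designs with an arbitrary number of factors and levels.
    Each main effect and interaction is tested by its own stacked regression
    on a reduced (contrast-projected) data matrix, with Greenhouse-Geisser
    sphericity correction and partial eta squared. Interactions with
    categorical between-subject group factors and with continuous
    between-subject covariates are tested via centered contrast
    multiplication; adding between-subject terms never changes the
    within-subject results. Non-parametric p-values are available through
    per-participant sign-flip randomization and covariate permutation.
    Significant interactions are unpacked automatically into recursive
    simple-effect tests and pairwise paired t-tests. A null-simulation
    harness with a tunable between-condition dependency factor verifies
    false-positive-rate control.
License: MIT
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
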