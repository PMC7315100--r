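---
title: "Effect-wise repeated-measures ANOVA: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effect-wise repeated-measures ANOVA: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmaov)
```

## The model

`rmaov` tests every main effect and interaction of an N-way within-subject
factorial design with its own, self-contained regression. The input is a
subjects × cells matrix in which later factors are nested inside earlier
ones over columns (the first factor varies slowest), plus the vector of
level counts.

For each effect three steps are performed.

**1. Effect coding.** Each factor with L levels is represented by L−1
contrast columns over the design cells: cells at the factor's first level
are coded −1, cells at level n are coded +1 in the n-th column, all other
cells 0. An interaction's coding matrix contains the elementwise products
of the involved factors' contrast columns, one column per combination of
contrasts, the last factor's contrast index varying fastest (the same
nesting rule as the cells). Every coding column sums to zero over cells,
and across all 2^N − 1 effects the column counts add up to the full
between-cell degrees of freedom, `prod(levels) − 1`.

**2. Reduction.** Each subject's row is centered and replaced by its
orthogonal projection onto the effect's contrast space (a per-row least
squares regression with the coding columns as predictors, keeping the
fitted values). The reduced data matrix carries only the variability
relevant to the tested effect; it is idempotent under re-reduction and its
rows sum to zero.

**3. Stacked regression and F-test.** The reduced matrix is vectorized
column-major, the coding columns are replicated per subject so each entry
meets the right cell, all columns are centered, and the data vector is
regressed onto the stacked coding columns without an intercept (effects
are symmetric around zero by construction). With q coding columns and N
subjects, the F-ratio of mean-square model to mean-square error is
referred to an F distribution on (q, (N−1)·q) degrees of freedom; partial
eta squared is `ss_model / (ss_model + ss_error)`.

**Sphericity.** When q > 1 the p-value assumes equal variances of all
pairwise condition differences. Departures are corrected in the
Greenhouse–Geisser manner: with L the eigenvalue spectrum of the
covariance matrix of the reduced data matrix and d the number of non-zero
eigenvalues, `epsilon = sum(L)^2 / (d * sum(L^2))`, and both degrees of
freedom are multiplied by epsilon before the tail probability is taken.
Epsilon is 1 for a spherical spectrum and at least 1/d in general. For
q = 1 no correction applies (`epsilon = 1` exactly). Huynh–Feldt or
lower-bound corrections are not implemented.

## Between-subject variables

Every test is built per effect, so adding between-subject variables
changes nothing about the within-subject results — this is deliberate and
differs from pooled-model (e.g. ANCOVA-style) formulations, which share an
error term across effects and therefore shift when covariates enter.

*Categorical group factors* are effect-coded over subjects exactly like
within-subject factors, and each contrast column is centered. The
group × within interaction regresses the within-reduced data onto the
products of the stacked within contrasts and the subject's centered group
scores, with model df `q·(k−1)` and error df `(N−k)·q`. Centering the
group scores is essential: without it a genuine within-subject effect
combined with unequal group sizes leaks into the product predictors and
inflates the interaction's false-positive rate (this is demonstrated in
the test suite). A consequence of the effect-wise construction worth
knowing: the grand (group-averaged) within-effect is orthogonal to the
centered product predictors and therefore remains in the residual, so in
the presence of a strong common within-effect the interaction test is
conservative rather than exactly alpha-level. Under a global null it is
alpha-exact.

*Continuous covariates* (cv) are centered and multiplied into each
subject's stacked contrast values; the regression then proceeds exactly as
for the within-subject effect (df q and (N−1)·q). The test asks whether
the size of the within-subject effect depends linearly on the covariate.
Correlation follow-ups (cv against each condition spanned by the effect
and against each pairwise condition difference, uncorrected) are attached
for descriptive exploration. Group main effects are reported as a plain
one-way ANOVA on subject means; between × between interactions are not
defined by this method and are not implemented.

## Randomization tests

The non-parametric variant replaces the F distribution with a Monte-Carlo
null. For within-subject effects, each iteration flips the sign of every
subject's reduced row with probability 1/2 (`signflip_test()`); flipping a
whole row is an isometry, so all between-column dependencies are
preserved and only the exchangeability of each subject's effect direction
is assumed. For covariate interactions the covariate values are permuted
across subjects instead (`cv_permutation_test()`). The p-value is the
plain proportion of null F values at or above the observed one, ties
included; a p of exactly 0 is therefore possible and is flagged, and a
smoothed `(hits + 1) / (iterations + 1)` estimate is available via
`smoothed = TRUE`. One seeded generator drives each test invocation, with
subject draws ordered within iteration, so results are reproducible and
independent of any parallel scheduling. Exhaustive enumeration of all 2^N
sign patterns is out of scope; the Monte-Carlo estimate's granularity is
1/iterations.

## Unpacking interactions

Significant interactions are decomposed descriptively in two ways
(`unpack_interaction()`, `pairwise_tests()`). First, recursively: for each
level of the last involved factor (the one with the highest design index)
the data are sliced to that level's cells and the next-lower-order
interaction among the remaining involved factors is tested, down to simple
effects of a single factor at a fully specified combination of the other
involved factors' levels. Second, two-sided paired t-tests on N−1 df are
run between all conditions spanned by the involved factors, marginalizing
over uninvolved factors. Neither set is corrected for multiple
comparisons: they are protected by the significant parent interaction and
serve description, not confirmation. `rm_anova()` builds the trees for
every interaction and flags them `protected` when the parent's p falls
below `alpha` (default 0.05).

## The null-data generator

`simulate_null_data()` emulates the kind of data the method is meant for
while containing no true effect of any kind: standard-normal scores per
subject and cell, group membership assigned as `floor(k·uniform) + 1`
(random, generally unbalanced group sizes; a balanced option exists for
tests), and a standard-normal covariate. Correlation between conditions —
the situation that stresses the sphericity correction — is induced by a
dependency factor `dep`: a uniformly random half of the columns
(`floor(cells/2)`) is each replaced by `(1−dep)` times itself plus `dep`
times the row-wise mean of the other columns. All replacements read the
pre-mixing matrix (simultaneous update), so the result does not depend on
the order in which columns are processed. At `dep = 0` columns stay
independent; at `dep = 1` each selected column equals the mean of the
others exactly.

What the generator does not emulate: non-normal (skewed, heavy-tailed,
bounded) scores, heterogeneous variances across cells beyond what the
mixing induces, missing data, and trial-level noise aggregated into cell
means. Passing null-rate tests on these data therefore shows calibration
under normality with correlated conditions, not robustness to arbitrary
real-data pathologies — the randomization tests exist precisely for the
cases where normality is in doubt.

`fpr_study()` sweeps `dep` over a grid (default 0 to 1 in steps of 0.1)
and records, per dependency and per effect type (within mains and
interactions, each group × within, cv × within), the proportion of
parametric p-values below alpha and the mean p-value. The package's
reference configuration mirrors a two-factor 3 × 4 within design with two
3-level group factors and one covariate at n = 36 subjects — a sample size
typical of the experimental studies this method serves, chosen once and
kept fixed. The acceptance script and test suite run this grid at 2,000
iterations per dependency factor, judged with a three-binomial-SE
Monte-Carlo allowance; the study can be scaled to larger iteration counts
by the `iterations` argument.

## Numerical choices

- Projections use an SVD-based pseudoinverse with a relative rank
  tolerance of 1e−10, so non-orthogonal (as the −1/0/+1 scheme is, for
  L > 2) or even linearly dependent coding columns are handled; any
  invertible recombination of an effect's contrast columns leaves F, p,
  epsilon and partial eta squared unchanged.
- "Non-zero" eigenvalues in the epsilon formula are those above
  `max(eigenvalue) · 1e−10`; an all-zero reduced matrix yields
  epsilon = 1 with a degenerate-data warning.
- The covariance for epsilon is the sample covariance (divisor N−1) of
  the reduced matrix's columns; subject means are already removed by the
  row-centering step. For group and covariate interactions epsilon comes
  from the same within-reduced matrix — scaling rows by subject-level
  scores does not change the sphericity structure being corrected for.
- `ss_error = 0` (noiseless data) reports an infinite F with p = 0 and
  partial eta squared 1, with a warning; `ss_model = 0` reports F = 0,
  p = 1.
- Rows containing any missing value are dropped listwise with a warning,
  both at CSV ingestion and inside `test_within_effect()`.
- P-values are stored at full double precision; printing uses scientific
  notation below 1e−4 and four decimals otherwise, with epsilon and
  partial eta squared at three decimals.

## Known limitations

Unbalanced within-subject designs (unequal cell structure), Huynh–Feldt
correction, multivariate (MANOVA) formulations, non-parametric tests for
categorical group interactions (the randomization scheme is defined for
sign flips and covariate permutation only), and unpacking across group
factors are all out of scope. The effect-wise philosophy trades the noise
reduction of a pooled ANCOVA for independence of tests; results will
differ slightly from pooled-model software by design.
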