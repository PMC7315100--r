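# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: brute-force least squares via normal equations,
# the textbook two-way RM decomposition, and stats:: reference tests.

# classical univariate RM-ANOVA for a single within factor on an
# n x L matrix: effect MS over (effect x subject) MS
oracle_rm_oneway_F <- function(x) {
  n <- nrow(x); L <- ncol(x)
  grand <- mean(x)
  colm <- colMeans(x)
  rowm <- rowMeans(x)
  ss_effect <- n * sum((colm - grand)^2)
  resid <- x - outer(rowm, rep(1, L)) - outer(rep(1, n), colm) + grand
  ss_inter <- sum(resid^2)
  (ss_effect / (L - 1)) / (ss_inter / ((n - 1) * (L - 1)))
}

# brute-force least squares on the stacked system via normal equations
oracle_stacked_ss <- function(reduced, X) {
  n <- nrow(reduced)
  y <- as.vector(reduced)
  Z <- X[rep(seq_len(nrow(X)), each = n), , drop = FALSE]
  y <- y - mean(y)
  Z <- sweep(Z, 2, colMeans(Z))
  b <- qr.solve(crossprod(Z), crossprod(Z, y))
  fitted <- Z %*% b
  list(ss_model = sum(fitted^2), ss_error = sum((y - fitted)^2))
}

# marginal means of a 2-level factor in a nested design, for the t^2 oracle
oracle_marginal_means <- function(data, levels, factor) {
  ct <- rmaov::enumerate_cells(levels)
  lev <- ct[factor, ]
  vapply(seq_len(max(lev)), function(l) {
    rowMeans(data[, lev == l, drop = FALSE])
  }, numeric(nrow(data)))
}

random_design <- function(max_factors = 4, max_levels = 4) {
  nf <- sample(1:max_factors, 1)
  sample(2:max_levels, nf, replace = TRUE)
}
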