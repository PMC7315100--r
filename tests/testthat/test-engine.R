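test_that("worked reduction example gives 2/3 magnitudes, alternating signs", {
  cod <- main_effect_coding(enumerate_cells(c(3, 2)), 2)
  red <- reduce_rows(matrix(c(-2, 4, 3, -7, 1, 1), nrow = 1), cod)
  expect_equal(abs(as.vector(red)), rep(2 / 3, 6), tolerance = 1e-12)
  # projection orientation: raw row favours the -1-coded cells on average
  # (mean of +1 cells minus mean of -1 cells is -4/3), so the first,
  # -1-coded, cell is predicted positive
  expect_equal(as.vector(red), c(1, -1, 1, -1, 1, -1) * 2 / 3,
               tolerance = 1e-12)
})

test_that("reduction is a centered projection", {
  cod <- enumerate_effects(c(2, 3))
  # constant rows vanish
  expect_equal(reduce_rows(matrix(5, 2, 6), cod[["W2"]]),
               matrix(0, 2, 6))
  # full contrast basis reproduces the centered data
  set.seed(7)
  x <- matrix(rnorm(4 * 6), 4, 6)
  full <- do.call(cbind, lapply(cod, function(e) e$matrix))
  red <- reduce_rows(x, full)
  expect_equal(red, x - rowMeans(x), tolerance = 1e-10)
  # idempotence and zero row sums for every effect
  for (e in cod) {
    r1 <- reduce_rows(x, e)
    expect_equal(reduce_rows(r1, e), r1, tolerance = 1e-10)
    expect_equal(rowSums(r1), rep(0, 4), tolerance = 1e-10)
  }
  expect_error(reduce_rows(x, matrix(numeric(0), 6, 0)), "no columns")
  expect_error(reduce_rows(x[, 1:5], cod[["W1"]]), "columns")
})

test_that("stacked regression decomposes the total sum of squares", {
  set.seed(11)
  effs <- enumerate_effects(c(2, 3))
  x <- matrix(rnorm(8 * 6), 8, 6)
  for (e in effs) {
    red <- reduce_rows(x, e)
    ss <- stacked_regression(red, e)
    orc <- oracle_stacked_ss(red, e$matrix)
    expect_equal(ss$ss_model, orc$ss_model, tolerance = 1e-8)
    expect_equal(ss$ss_error, orc$ss_error, tolerance = 1e-8)
    yc <- as.vector(red) - mean(as.vector(red))
    expect_equal(ss$ss_model + ss$ss_error, sum(yc^2), tolerance = 1e-8)
  }
  # identical rows: all variance explained by the effect
  red1 <- reduce_rows(matrix(rep(rnorm(6), each = 4), 4, 6), effs[["W2"]])
  expect_lt(stacked_regression(red1, effs[["W2"]])$ss_error, 1e-16)
  # +v / -v rows cancel: no model sum of squares
  v <- reduce_rows(matrix(rnorm(6), 1, 6), effs[["W1"]])
  red2 <- rbind(v, -v, v, -v)
  expect_lt(stacked_regression(red2, effs[["W1"]])$ss_model, 1e-16)
})

test_that("epsilon follows the eigenvalue formula", {
  # exact sample covariance diag(3, 1): centered orthogonal columns with
  # crossprod = (n-1) * diag(3, 1) -> spectrum (3, 1) -> 16 / (2 * 10)
  m31 <- cbind(c(-1.5, 1.5, -1.5, 1.5),
               sqrt(3) / 2 * c(-1, -1, 1, 1))
  gg <- gg_epsilon(m31)
  expect_equal(gg$epsilon, 0.8, tolerance = 1e-12)
  expect_equal(gg$eigenvalues, c(3, 1), tolerance = 1e-12)
  # equal eigenvalues -> 1
  meq <- cbind(c(-1, 1, -1, 1), c(-1, -1, 1, 1))
  expect_equal(gg_epsilon(meq)$epsilon, 1, tolerance = 1e-12)
  # a single non-zero eigenvalue -> 1
  expect_equal(gg_epsilon(cbind(c(-2, 2), c(-4, 4)))$epsilon, 1,
               tolerance = 1e-12)
  # degenerate all-zero matrix -> 1 with a warning
  expect_warning(gg <- gg_epsilon(matrix(0, 3, 4)), "zero variance")
  expect_equal(gg$epsilon, 1)
  # bounds: epsilon in [1/d, 1] on random reduced data
  set.seed(13)
  e <- enumerate_effects(c(2, 4))[["W2"]]
  red <- reduce_rows(matrix(rnorm(10 * 8), 10, 8), e)
  gg <- gg_epsilon(red)
  expect_gte(gg$epsilon, 1 / gg$nonzero_count)
  expect_lte(gg$epsilon, 1)
})

test_that("F-test handles degenerate sums of squares", {
  r <- f_test(3, 3, 4, 4)
  expect_equal(r$F, 1)
  r0 <- f_test(0, 5, 2, 10)
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$partial_eta2, 0)
  expect_warning(rinf <- f_test(5, 0, 2, 10), "infinite")
  expect_equal(rinf$F, Inf)
  expect_equal(rinf$p, 0)
  expect_equal(rinf$partial_eta2, 1)
})

test_that("2-level effects reproduce the paired t-test exactly", {
  set.seed(17)
  for (rep in 1:25) {
    lv <- c(2, sample(2:4, 1))
    n <- sample(6:20, 1)
    x <- matrix(rnorm(n * prod(lv)), n)
    eff <- enumerate_effects(lv)[[1]]
    r <- test_within_effect(x, eff)
    mm <- oracle_marginal_means(x, lv, 1)
    tt <- t.test(mm[, 2], mm[, 1], paired = TRUE)
    expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(r$p, tt$p.value, tolerance = 1e-10)
    expect_equal(r$epsilon, 1)  # single contrast: no sphericity correction
  }
})

test_that("multi-level effects reproduce the classical RM decomposition", {
  set.seed(19)
  for (rep in 1:25) {
    L <- sample(3:5, 1)
    n <- sample(6:20, 1)
    x <- matrix(rnorm(n * L), n, L)
    eff <- enumerate_effects(c(L))[[1]]
    r <- test_within_effect(x, eff)
    expect_equal(r$F, oracle_rm_oneway_F(x), tolerance = 1e-8)
    expect_equal(r$df_model, L - 1)
    expect_equal(r$df_error, (n - 1) * (L - 1))
  }
})

test_that("results are invariant to invertible recoding of the contrasts", {
  set.seed(23)
  eff <- enumerate_effects(c(2, 3))[["W2"]]
  x <- matrix(rnorm(9 * 6), 9, 6)
  base <- test_within_effect(x, eff)
  A <- matrix(c(2, 1, 0.5, -1), 2, 2)  # invertible recombination
  recoded <- eff
  recoded$matrix <- eff$matrix %*% A
  alt <- test_within_effect(x, recoded)
  expect_equal(alt$F, base$F, tolerance = 1e-8)
  expect_equal(alt$p, base$p, tolerance = 1e-8)
  expect_equal(alt$epsilon, base$epsilon, tolerance = 1e-8)
  expect_equal(alt$partial_eta2, base$partial_eta2, tolerance = 1e-8)
})

test_that("effects are unaffected by variance in orthogonal contrast spaces", {
  set.seed(29)
  effs <- enumerate_effects(c(2, 3))
  x <- matrix(rnorm(10 * 6), 10, 6)
  base <- test_within_effect(x, effs[["W1"]])
  # add an arbitrary pattern living in the other factor's contrast space
  shift <- reduce_rows(matrix(rnorm(10 * 6), 10, 6), effs[["W2"]])
  alt <- test_within_effect(x + shift, effs[["W1"]])
  expect_equal(alt$F, base$F, tolerance = 1e-8)
  expect_equal(alt$p, base$p, tolerance = 1e-8)
})

test_that("missing and undersized inputs are handled", {
  effs <- enumerate_effects(c(2))
  expect_error(test_within_effect(matrix(1:2, 1, 2), effs[[1]]), "2 subjects")
  x <- matrix(rnorm(12), 6, 2)
  x[3, 1] <- NA
  expect_warning(r <- test_within_effect(x, effs[[1]]), "missing")
  expect_equal(r$n_subjects, 5)
})

test_that("null data yield approximately uniform parametric p-values", {
  set.seed(31)
  effs <- enumerate_effects(c(2, 3))
  reps <- 2000
  pvals <- matrix(NA_real_, reps, length(effs))
  for (i in seq_len(reps)) {
    x <- matrix(rnorm(20 * 6), 20, 6)
    for (j in seq_along(effs))
      pvals[i, j] <- test_within_effect(x, effs[[j]])$p
  }
  mc3 <- 3 * sqrt(0.05 * 0.95 / reps)
  for (j in seq_along(effs)) {
    expect_lt(abs(mean(pvals[, j] < 0.05) - 0.05), mc3)
    expect_gt(suppressWarnings(ks.test(pvals[, j], "punif"))$p.value, 1e-4)
  }
})
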