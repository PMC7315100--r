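test_that("group coding is centered effect coding over subjects", {
  g <- group_coding(c("a", "a", "b", "b", "c", "c"))
  expect_equal(g$k, 3)
  expect_equal(colSums(g$coding), c(0, 0), tolerance = 1e-12)
  # balanced groups: centering leaves the -1/0/1 pattern intact
  expect_equal(unname(g$coding),
               cbind(c(-1, -1, 1, 1, 0, 0), c(-1, -1, 0, 0, 1, 1)))
  expect_error(group_coding(rep("a", 5)), "at least 2 groups")
  expect_warning(group_coding(c("a", "b", "b", "b")), "fewer than 2")
})

test_that("group x within interaction detects and rejects as it should", {
  effs <- enumerate_effects(c(2))
  v <- c(-1, 1) * 0.5
  # identical within-effect in both groups: zero interaction
  x <- matrix(rep(v, each = 8), 8, 2) + rnorm(8)  # subject offsets only
  r <- test_within_by_group(x, effs[[1]], rep(c(1, 2), each = 4))
  expect_lt(r$ss_model, 1e-12)
  expect_lt(r$F, 1e-10)
  # perfect crossover, noiseless: essentially zero error
  x2 <- rbind(matrix(rep(v, each = 4), 4, 2),
              matrix(rep(-v, each = 4), 4, 2))
  r2 <- test_within_by_group(x2, effs[[1]], rep(c(1, 2), each = 4))
  expect_gt(r2$F, 1e10)
  expect_lt(r2$p, 1e-12)
  # df rule: (N - k) * q
  set.seed(41)
  x3 <- matrix(rnorm(12 * 6), 12, 6)
  eff23 <- enumerate_effects(c(2, 3))[["W2"]]
  r3 <- test_within_by_group(x3, eff23, rep(c(1, 2, 3), 4))
  expect_equal(r3$df_model, 2 * (3 - 1))
  expect_equal(r3$df_error, (12 - 3) * 2)
  expect_error(suppressWarnings(test_within_by_group(x3[1:2, ], eff23,
                                                     c(1, 2))), "groups")
})

test_that("group x within null rejection rate is controlled", {
  set.seed(43)
  eff <- enumerate_effects(c(2))[[1]]
  reps <- 2000
  p <- numeric(reps)
  for (i in seq_len(reps)) {
    x <- matrix(rnorm(40 * 2), 40, 2)
    p[i] <- test_within_by_group(x, eff, rep(c(1, 2), each = 20))$p
  }
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("centering the group scores is what keeps the null honest", {
  # with a strong common within-effect and unbalanced groups, uncentered
  # scores leak the main effect into the interaction predictor
  set.seed(47)
  eff <- enumerate_effects(c(2))[[1]]
  n <- 30
  labels <- rep(c(1, 2), c(22, 8))
  reps <- 600
  p_cen <- numeric(reps); p_unc <- numeric(reps)
  uncentered_scores <- cbind(ifelse(labels == 1, -1, 1))
  for (i in seq_len(reps)) {
    x <- matrix(rnorm(n * 2), n, 2)
    x[, 2] <- x[, 2] + 2  # common within-subject effect, same in both groups
    p_cen[i] <- test_within_by_group(x, eff, labels)$p
    red <- reduce_rows(x, eff)
    Z <- rmaov:::interaction_predictors(eff$matrix, uncentered_scores, n)
    ss <- stacked_regression(red, eff, predictors = Z)
    p_unc[i] <- f_test(ss$ss_model, ss$ss_error, 1, n - 2)$p
  }
  tol <- 3 * sqrt(0.05 * 0.95 / reps)
  # centered: no inflation (the grand within-effect sits in the residual,
  # so the test errs on the conservative side when such an effect exists)
  expect_lte(mean(p_cen < 0.05), 0.05 + tol)
  expect_gt(mean(p_unc < 0.05), 0.05 + tol)  # inflated without centering
})

test_that("cv interaction follows the within pipeline with scaled predictors", {
  effs <- enumerate_effects(c(2))
  x <- matrix(rnorm(10 * 2), 10, 2)
  expect_error(test_within_by_cv(x, effs[[1]], rep(3, 10)), "constant")
  # effect strictly proportional to cv, noiseless: p -> 0
  cv <- seq(-2, 2, length.out = 10)
  x2 <- cbind(-cv, cv) + rnorm(10)
  r <- test_within_by_cv(x2, effs[[1]], cv)
  expect_lt(r$p, 1e-12)
  # df rule matches the within test
  set.seed(53)
  eff23 <- enumerate_effects(c(2, 3))[["W2"]]
  x3 <- matrix(rnorm(12 * 6), 12, 6)
  r3 <- test_within_by_cv(x3, eff23, rnorm(12))
  expect_equal(r3$df_model, 2)
  expect_equal(r3$df_error, (12 - 1) * 2)
  # shifting the cv by a constant changes nothing
  cv3 <- rnorm(12)
  a <- test_within_by_cv(x3, eff23, cv3)
  b <- test_within_by_cv(x3, eff23, cv3 + 100)
  expect_equal(a$F, b$F, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
})

test_that("cv x within null rejection rate is controlled", {
  set.seed(59)
  eff <- enumerate_effects(c(2, 2))[["W1:W2"]]
  reps <- 2000
  p <- numeric(reps)
  for (i in seq_len(reps)) {
    x <- matrix(rnorm(25 * 4), 25, 4)
    p[i] <- test_within_by_cv(x, eff, rnorm(25))$p
  }
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("adding between-subject terms leaves within results bit-identical", {
  set.seed(61)
  for (rep in 1:5) {
    lv <- random_design(max_factors = 3, max_levels = 3)
    n <- sample(10:20, 1)
    x <- matrix(rnorm(n * prod(lv)), n)
    within <- stats::setNames(lv, paste0("F", seq_along(lv)))
    fit0 <- rm_anova(x, within)
    fit1 <- rm_anova(x, within,
                     between = sample(1:2, n, replace = TRUE),
                     cv = rnorm(n))
    w0 <- fit0$effects
    w1 <- fit1$effects[fit1$effects$type == "within", ]
    rownames(w1) <- NULL
    expect_identical(w0, w1)
  }
})

test_that("cv follow-up correlations match the stats:: oracle", {
  set.seed(67)
  lv <- c(2, 3)
  x <- matrix(rnorm(15 * 6), 15, 6)
  cv <- rnorm(15)
  fu <- cv_followups(x, lv, 2, cv)
  # factor 2 spans 3 conditions -> 3 condition rows + 3 contrast rows
  expect_equal(nrow(fu), 6)
  expect_equal(sum(fu$type == "condition"), 3)
  # conditions marginalize over factor 1 with the nesting convention
  cond2 <- rowMeans(x[, c(2, 5)])
  ct <- cor.test(cv, cond2)
  expect_equal(fu$r[fu$type == "condition"][2], unname(ct$estimate),
               tolerance = 1e-12)
  expect_equal(fu$p[fu$type == "condition"][2], ct$p.value,
               tolerance = 1e-12)
  # a cv equal to a condition column correlates 1 with it
  fu2 <- cv_followups(x, lv, 2, cond2)
  expect_equal(fu2$r[fu2$type == "condition"][2], 1, tolerance = 1e-12)
})
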