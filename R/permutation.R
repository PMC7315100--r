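#' Sign-flip randomization test of a within-subject effect
#'
#' Builds a non-parametric null distribution for a within-subject effect by
#' randomly reversing, with 50% chance per participant and iteration, the
#' direction of that participant's within-subject effect (their row of the
#' reduced data matrix). Flipping a whole row preserves the dependencies
#' between columns exactly, so the null embodies only the hypothesis that
#' the sign of each subject's effect is exchangeable. The stacked-regression
#' F is recomputed per iteration; the permutation p-value is the proportion
#' of null F values greater than or equal to the observed F (ties count).
#'
#' With the plain proportion a p-value of exactly 0 is possible;
#' `smoothed = TRUE` switches to the (count + 1) / (iterations + 1) variant.
#'
#' @param data Subjects x cells data matrix.
#' @param coding `effect_coding` of the tested effect.
#' @param iterations Number of random sign assignments (e.g. 10000).
#' @param seed Optional integer seed for reproducibility.
#' @param smoothed Use the add-one p-value estimate. Default `FALSE`.
#' @return An object of class `rm_null_dist`: list with `observed_f`,
#'   `f_values` (length `iterations`), `p_perm`, and `iterations`.
#' @export
signflip_test <- function(data, coding, iterations = 1000L, seed = NULL,
                          smoothed = FALSE) {
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  data <- as_data_matrix(data)
  n <- nrow(data)
  if (n < 2L) stop("at least 2 subjects required", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  reduced <- reduce_rows(data, coding)
  X <- coding_matrix(coding)
  obs <- stacked_f(reduced, X, n)
  fnull <- numeric(iterations)
  for (i in seq_len(iterations)) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    fnull[i] <- stacked_f(reduced * flips, X, n)
  }
  perm_result(obs, fnull, smoothed)
}

# F ratio of the stacked regression on replicated coding columns; dfs are
# constant across sign flips, so the plain SS ratio orders iterations
stacked_f <- function(reduced, X, n_subjects) {
  ss <- stacked_regression(reduced, X)
  q <- ncol(X)
  dfe <- (n_subjects - 1) * q
  if (ss$ss_error <= 0) return(Inf)
  (ss$ss_model / q) / (ss$ss_error / dfe)
}

perm_result <- function(obs, fnull, smoothed) {
  hits <- sum(fnull >= obs)
  p <- if (smoothed) (hits + 1) / (length(fnull) + 1) else hits / length(fnull)
  structure(list(observed_f = obs, f_values = fnull, p_perm = p,
                 iterations = length(fnull)),
            class = "rm_null_dist")
}

#' @export
print.rm_null_dist <- function(x, ...) {
  cat(sprintf("Randomization test: observed F = %s, p = %s (%d iterations)\n",
              format(x$observed_f, digits = 4), format_p(x$p_perm),
              x$iterations))
  invisible(x)
}

#' Permutation test of a covariate-by-within interaction
#'
#' Non-parametric p-value for the interaction of a within-subject effect
#' with a continuous between-subject variable: per iteration the covariate
#' values are randomly permuted across subjects, severing any systematic
#' link between the covariate and the within-subject effects, and the
#' interaction F from [test_within_by_cv()]'s regression is recomputed.
#' The p-value is the proportion of null F values at or above the observed.
#'
#' @inheritParams signflip_test
#' @param cv Per-subject numeric covariate; must not be constant.
#' @return An `rm_null_dist` object.
#' @export
cv_permutation_test <- function(data, coding, cv, iterations = 1000L,
                                seed = NULL, smoothed = FALSE) {
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  data <- as_data_matrix(data)
  n <- nrow(data)
  cv <- as.numeric(cv)
  cvc <- cv - mean(cv)
  if (all(cvc == 0)) stop("cv is constant (zero variance)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  reduced <- reduce_rows(data, coding)
  X <- coding_matrix(coding)
  obs <- cv_f(reduced, X, cvc, n)
  fnull <- numeric(iterations)
  for (i in seq_len(iterations)) {
    fnull[i] <- cv_f(reduced, X, cvc[sample.int(n)], n)
  }
  perm_result(obs, fnull, smoothed)
}

cv_f <- function(reduced, X, cvc, n_subjects) {
  Z <- interaction_predictors(X, cbind(cvc), n_subjects)
  ss <- stacked_regression(reduced, X, predictors = Z)
  q <- ncol(X)
  dfe <- (n_subjects - 1) * q
  if (ss$ss_error <= 0) return(Inf)
  (ss$ss_model / q) / (ss$ss_error / dfe)
}
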