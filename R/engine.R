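#' Reduce a data matrix to one effect's contrast space
#'
#' Each row (subject) of the data matrix is centered (its own mean
#' subtracted) and then replaced by its orthogonal projection onto the
#' column space of the effect-coding matrix — the least-squares prediction
#' of the centered row from the contrast columns. The result, the reduced
#' data matrix, retains only the between-cell variability relevant to the
#' tested effect; variance in orthogonal contrast spaces is removed.
#' The operation is idempotent and every output row sums to zero.
#'
#' @param data Numeric matrix, subjects in rows, design cells in columns.
#' @param coding An `effect_coding` object whose matrix has one row per
#'   data column.
#' @return Numeric matrix of the same dimension as `data`.
#' @examples
#' ct <- enumerate_cells(c(3, 2))
#' cod <- main_effect_coding(ct, 2)
#' reduce_rows(matrix(c(-2, 4, 3, -7, 1, 1), nrow = 1), cod)
#' # every element 2/3 in absolute value, signs alternating
#' @export
reduce_rows <- function(data, coding) {
  data <- as_data_matrix(data)
  X <- coding_matrix(coding)
  if (ncol(X) == 0L) stop("effect coding has no columns", call. = FALSE)
  if (nrow(X) != ncol(data))
    stop("data has ", ncol(data), " columns but coding expects ", nrow(X),
         call. = FALSE)
  centered <- data - rowMeans(data)
  centered %*% projector(X)
}

# symmetric projector onto colspace(X); svd-based pseudoinverse tolerates
# rank-deficient or non-orthogonal coding columns
projector <- function(X) {
  s <- svd(X)
  keep <- s$d > max(s$d[1], 0) * 1e-10
  U <- s$u[, keep, drop = FALSE]
  tcrossprod(U)
}

as_data_matrix <- function(data) {
  m <- as.matrix(data)
  if (!is.numeric(m)) stop("data must be numeric", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

coding_matrix <- function(coding) {
  if (inherits(coding, "effect_coding")) coding$matrix
  else as.matrix(coding)
}

#' Stacked regression sums of squares for one effect
#'
#' The reduced data matrix is vectorized column-major (each cell's column of
#' subjects stacked under the previous one) and regressed, without
#' intercept, onto the effect-coding columns replicated per subject: for N
#' subjects the first N entries of a stacked predictor carry the coding's
#' value for cell 1, and so on. All columns are centered before the fit.
#' Returns the model sum of squares (squared fitted values) and error sum
#' of squares (squared residuals); the two add up to the total sum of
#' squares of the centered outcome.
#'
#' @param reduced Reduced data matrix from [reduce_rows()] (subjects x cells).
#' @param coding The same `effect_coding` used in the reduction, or a bare
#'   predictor matrix with one row per cell. Alternatively `predictors` may
#'   supply a pre-stacked predictor matrix with `nrow(reduced) * ncells`
#'   rows (used for between-subject interaction terms, whose predictors
#'   vary by subject).
#' @param predictors Optional pre-stacked predictor matrix overriding
#'   `coding`.
#' @return List with `ss_model` and `ss_error`.
#' @export
stacked_regression <- function(reduced, coding, predictors = NULL) {
  reduced <- as_data_matrix(reduced)
  y <- as.vector(reduced)           # column-major: subject-fastest
  Z <- if (is.null(predictors)) {
    X <- coding_matrix(coding)
    stack_coding(X, nrow(reduced))
  } else {
    as.matrix(predictors)
  }
  if (nrow(Z) != length(y))
    stop("stacked predictor rows do not match vectorized data length",
         call. = FALSE)
  y <- y - mean(y)
  Z <- sweep(Z, 2L, colMeans(Z))
  fit <- stats::lm.fit(Z, y)
  sse <- sum(fit$residuals^2)
  ssm <- sum(y^2) - sse
  list(ss_model = max(ssm, 0), ss_error = sse)
}

# replicate each coding row n_subjects times, matching as.vector() stacking
stack_coding <- function(X, n_subjects) {
  X[rep(seq_len(nrow(X)), each = n_subjects), , drop = FALSE]
}

#' Greenhouse-Geisser epsilon from the reduced data matrix
#'
#' Sphericity departure is measured on the eigenvalue spectrum L of the
#' covariance matrix of the reduced data matrix:
#' `epsilon = sum(L)^2 / (d * sum(L^2))`, with d the number of non-zero
#' eigenvalues (those above `max(L) * 1e-10`). Epsilon is 1 for a
#' spherical spectrum (all non-zero eigenvalues equal) and falls towards
#' `1/d` as the spectrum concentrates. Model and error degrees of freedom
#' are multiplied by epsilon before the F-test when the effect has more
#' than one contrast column.
#'
#' @param reduced Reduced data matrix (subjects x cells), at least 2 rows.
#' @return List with `epsilon`, `eigenvalues` (non-increasing), and
#'   `nonzero_count`.
#' @examples
#' # spectrum (3, 1): epsilon = (3+1)^2 / (2 * (9+1)) = 0.8
#' @export
gg_epsilon <- function(reduced) {
  reduced <- as_data_matrix(reduced)
  if (nrow(reduced) < 2L)
    stop("epsilon needs at least 2 subjects", call. = FALSE)
  V <- stats::cov(reduced)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (max(ev) <= 0) {
    warning("reduced data matrix has zero variance; epsilon set to 1")
    return(list(epsilon = 1, eigenvalues = ev, nonzero_count = 0L))
  }
  keep <- ev > max(ev) * 1e-10
  d <- sum(keep)
  eps <- sum(ev)^2 / (d * sum(ev^2))
  list(epsilon = min(eps, 1), eigenvalues = ev, nonzero_count = d)
}

#' F-test of an effect from its sums of squares
#'
#' Computes `F = (ss_model/df_model) / (ss_error/df_error)` and the
#' upper-tail p-value of the F distribution with
#' `(epsilon * df_model, epsilon * df_error)` degrees of freedom.
#' Partial eta squared is `ss_model / (ss_model + ss_error)`. Epsilon
#' should be 1 for single-contrast effects (no sphericity assumption with
#' one degree of freedom); callers pass the Greenhouse-Geisser value only
#' when `df_model > 1`.
#'
#' @param ss_model,ss_error Model and error sums of squares.
#' @param df_model,df_error Uncorrected degrees of freedom.
#' @param epsilon Sphericity correction factor in (0, 1].
#' @return List with `F`, `p`, `partial_eta2`, plus the inputs.
#' @export
f_test <- function(ss_model, ss_error, df_model, df_error, epsilon = 1) {
  stopifnot(df_model > 0, df_error > 0, epsilon > 0, epsilon <= 1)
  if (ss_error <= 0) {
    warning("zero error sum of squares; F is infinite")
    return(list(F = Inf, p = 0,
                partial_eta2 = if (ss_model > 0) 1 else NaN,
                df_model = df_model, df_error = df_error, epsilon = epsilon,
                ss_model = ss_model, ss_error = ss_error))
  }
  Fv <- (ss_model / df_model) / (ss_error / df_error)
  p <- stats::pf(Fv, epsilon * df_model, epsilon * df_error,
                 lower.tail = FALSE)
  list(F = Fv, p = p,
       partial_eta2 = ss_model / (ss_model + ss_error),
       df_model = df_model, df_error = df_error, epsilon = epsilon,
       ss_model = ss_model, ss_error = ss_error)
}

#' Test one within-subject effect
#'
#' Full pipeline for a single main effect or interaction: project each
#' subject's centered row onto the effect's contrast space
#' ([reduce_rows()]), estimate Greenhouse-Geisser epsilon from the reduced
#' matrix when the effect has more than one contrast column, run the
#' stacked regression ([stacked_regression()]), and perform the F-test.
#' Model df is the number of contrast columns q; error df is
#' `(n_subjects - 1) * q`.
#'
#' @param data Subjects x cells data matrix (nesting convention).
#' @param coding `effect_coding` for the tested effect.
#' @return An object of class `rm_effect_test`: the [f_test()] fields plus
#'   `effect` (factor indices), `n_subjects`, `eigenvalues`, and the
#'   `reduced` matrix (used by permutation tests and unpacking).
#' @examples
#' set.seed(1)
#' dat <- matrix(rnorm(8 * 6), 8, 6)
#' eff <- enumerate_effects(c(2, 3))
#' test_within_effect(dat, eff[["W2"]])
#' @export
test_within_effect <- function(data, coding) {
  data <- as_data_matrix(data)
  n <- nrow(data)
  if (n < 2L) stop("at least 2 subjects required", call. = FALSE)
  if (anyNA(data)) {
    drop <- apply(data, 1L, anyNA)
    warning("dropping ", sum(drop), " row(s) with missing values")
    data <- data[!drop, , drop = FALSE]
    n <- nrow(data)
    if (n < 2L) stop("fewer than 2 complete subjects", call. = FALSE)
  }
  reduced <- reduce_rows(data, coding)
  q <- ncol(coding_matrix(coding))
  gg <- if (q > 1L) gg_epsilon(reduced)
        else list(epsilon = 1, eigenvalues = NULL, nonzero_count = 1L)
  ss <- stacked_regression(reduced, coding)
  res <- f_test(ss$ss_model, ss$ss_error,
                df_model = q, df_error = (n - 1) * q,
                epsilon = gg$epsilon)
  res$effect <- if (inherits(coding, "effect_coding")) coding$factors else NA
  res$n_subjects <- n
  res$eigenvalues <- gg$eigenvalues
  res$reduced <- reduced
  class(res) <- "rm_effect_test"
  res
}

#' @export
print.rm_effect_test <- function(x, ...) {
  cat(sprintf(
    "F(%s, %s) = %s, p = %s, partial eta^2 = %s%s\n",
    format(x$epsilon * x$df_model, digits = 4),
    format(x$epsilon * x$df_error, digits = 4),
    format(x$F, digits = 4), format_p(x$p),
    formatC(x$partial_eta2, digits = 3, format = "f"),
    if (x$epsilon < 1) sprintf(", GG epsilon = %s",
                               formatC(x$epsilon, digits = 3, format = "f"))
    else ""))
  if (!is.null(x$p_perm))
    cat("  permutation p =", format_p(x$p_perm), "\n")
  invisible(x)
}

format_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 1e-4, formatC(p, digits = 2, format = "e"),
                formatC(p, digits = 4, format = "f")))
}
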