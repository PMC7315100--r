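#' Effect coding for a categorical between-subject factor
#'
#' Group membership is transformed into k-1 effect-coding contrast scores
#' per subject exactly as within-subject factors are coded (first group -1,
#' group n +1, others 0), and each contrast column is then centered over
#' subjects. Centering is essential: without it a genuine within-subject
#' effect combined with unequal group sizes would masquerade as a
#' group-by-within interaction.
#'
#' @param labels Per-subject group labels (factor, character, or integer).
#' @return List with `labels` (as factor), `k` (number of groups), and
#'   `coding` (subjects x (k-1) centered contrast scores).
#' @export
group_coding <- function(labels) {
  f <- as.factor(labels)
  f <- droplevels(f)
  k <- nlevels(f)
  if (k < 2L) stop("between-subject factor needs at least 2 groups",
                   call. = FALSE)
  if (any(table(f) < 2L))
    warning("a group has fewer than 2 subjects")
  idx <- as.integer(f)
  m <- vapply(2:k, function(n) {
    col <- numeric(length(idx))
    col[idx == 1L] <- -1
    col[idx == n] <- 1
    col
  }, numeric(length(idx)))
  m <- matrix(m, nrow = length(idx))
  m <- sweep(m, 2L, colMeans(m))
  list(labels = f, k = k, coding = m)
}

#' Test a group-by-within-subject interaction
#'
#' Whether a within-subject effect differs between groups is tested by
#' multiplying each element of the per-subject stacked effect-coding
#' predictors with that subject's centered group contrast scores: one
#' product predictor per (within contrast, group contrast) pair. The
#' stacked regression and F-test then proceed as for a pure within-subject
#' effect, with model df `q * (k - 1)` and error df `(N - k) * q`, where q
#' is the number of within contrast columns. Greenhouse-Geisser epsilon is
#' estimated from the within-reduced matrix when q > 1. Because the test
#' is built per effect, adding it never alters any within-subject result.
#'
#' @param data Subjects x cells data matrix.
#' @param coding `effect_coding` of the within-subject effect.
#' @param group Per-subject group labels, or the result of [group_coding()].
#' @return An `rm_effect_test` object (see [test_within_effect()]) with a
#'   `between` field naming the group term.
#' @export
test_within_by_group <- function(data, coding, group) {
  data <- as_data_matrix(data)
  n <- nrow(data)
  g <- if (is.list(group) && !is.null(group$coding)) group else group_coding(group)
  if (nrow(g$coding) != n)
    stop("group labels do not align with data rows", call. = FALSE)
  if (g$k >= n) stop("more groups than error degrees of freedom allow",
                     call. = FALSE)
  reduced <- reduce_rows(data, coding)
  q <- ncol(coding_matrix(coding))
  gg <- if (q > 1L) gg_epsilon(reduced)
        else list(epsilon = 1, eigenvalues = NULL)
  Z <- interaction_predictors(coding_matrix(coding), g$coding, n)
  ss <- stacked_regression(reduced, coding, predictors = Z)
  res <- f_test(ss$ss_model, ss$ss_error,
                df_model = q * (g$k - 1L), df_error = (n - g$k) * q,
                epsilon = gg$epsilon)
  res$effect <- if (inherits(coding, "effect_coding")) coding$factors else NA
  res$between <- "group"
  res$n_subjects <- n
  res$eigenvalues <- gg$eigenvalues
  res$reduced <- reduced
  class(res) <- "rm_effect_test"
  res
}

# stacked products: element (subject s, cell c) of column (j, b) is
# coding[c, j] * scores[s, b]; stacking is subject-fastest (column-major)
interaction_predictors <- function(X, scores, n_subjects) {
  n_cells <- nrow(X)
  q <- ncol(X)
  b <- ncol(scores)
  Z <- matrix(0, nrow = n_subjects * n_cells, ncol = q * b)
  col <- 0L
  for (j in seq_len(q)) {
    wj <- rep(X[, j], each = n_subjects)
    for (g in seq_len(b)) {
      col <- col + 1L
      Z[, col] <- wj * rep(scores[, g], times = n_cells)
    }
  }
  Z
}

#' Test a covariate-by-within-subject interaction
#'
#' Whether a within-subject effect depends linearly on a continuous
#' between-subject variable (cv) is tested by scaling every subject's
#' stacked effect-coding values by that subject's centered cv, then running
#' the identical stacked regression and F-test as for the within-subject
#' effect itself (model df q, error df `(N - 1) * q`). Shifting the cv by
#' any constant leaves the result unchanged.
#'
#' @param data Subjects x cells data matrix.
#' @param coding `effect_coding` of the within-subject effect.
#' @param cv Per-subject numeric covariate; must not be constant.
#' @return An `rm_effect_test` object with a `between` field of `"cv"`.
#' @export
test_within_by_cv <- function(data, coding, cv) {
  data <- as_data_matrix(data)
  n <- nrow(data)
  cv <- as.numeric(cv)
  if (length(cv) != n) stop("cv does not align with data rows", call. = FALSE)
  cvc <- cv - mean(cv)
  if (all(cvc == 0)) stop("cv is constant (zero variance)", call. = FALSE)
  reduced <- reduce_rows(data, coding)
  q <- ncol(coding_matrix(coding))
  gg <- if (q > 1L) gg_epsilon(reduced)
        else list(epsilon = 1, eigenvalues = NULL)
  Z <- interaction_predictors(coding_matrix(coding), cbind(cvc), n)
  ss <- stacked_regression(reduced, coding, predictors = Z)
  res <- f_test(ss$ss_model, ss$ss_error,
                df_model = q, df_error = (n - 1L) * q,
                epsilon = gg$epsilon)
  res$effect <- if (inherits(coding, "effect_coding")) coding$factors else NA
  res$between <- "cv"
  res$n_subjects <- n
  res$eigenvalues <- gg$eigenvalues
  res$reduced <- reduced
  class(res) <- "rm_effect_test"
  res
}

#' Correlation follow-ups for a covariate interaction
#'
#' Descriptive exploration of a significant cv-by-within interaction:
#' Pearson correlations (uncorrected) of the covariate with (a) each
#' condition spanned by the effect's factors (subject cell means,
#' marginalized over the uninvolved factors) and (b) every pairwise
#' difference between those conditions.
#'
#' @param data Subjects x cells data matrix.
#' @param design `rm_design` (or level-count vector) describing the columns.
#' @param factors Indices of the involved within-subject factors.
#' @param cv Per-subject numeric covariate.
#' @return Data frame with columns `type` ("condition" or "contrast"),
#'   `term`, `r`, and `p`.
#' @export
cv_followups <- function(data, design, factors, cv) {
  data <- as_data_matrix(data)
  cv <- as.numeric(cv)
  cells <- effect_cell_means(data, design, factors)
  labs <- colnames(cells)
  rows <- list()
  for (j in seq_len(ncol(cells))) {
    ct <- stats::cor.test(cv, cells[, j])
    rows[[length(rows) + 1L]] <- data.frame(
      type = "condition", term = labs[j],
      r = unname(ct$estimate), p = ct$p.value)
  }
  if (ncol(cells) > 1L) {
    prs <- utils::combn(ncol(cells), 2L)
    for (i in seq_len(ncol(prs))) {
      a <- prs[1L, i]; b <- prs[2L, i]
      d <- cells[, a] - cells[, b]
      if (stats::sd(d) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          type = "contrast", term = paste(labs[a], "-", labs[b]),
          r = NA_real_, p = NA_real_)
      } else {
        ct <- stats::cor.test(cv, d)
        rows[[length(rows) + 1L]] <- data.frame(
          type = "contrast", term = paste(labs[a], "-", labs[b]),
          r = unname(ct$estimate), p = ct$p.value)
      }
    }
  }
  do.call(rbind, rows)
}

# subject x involved-cell matrix of means, marginalizing over factors
# not in the effect; columns labelled by involved factors' level indices
effect_cell_means <- function(data, design, factors) {
  design <- as_rm_design(design)
  ct <- enumerate_cells(design)
  factors <- sort(as.integer(factors))
  sub <- ct[factors, , drop = FALSE]
  key <- apply(sub, 2L, paste, collapse = ",")
  ukey <- unique(key)  # in nesting order by construction
  out <- vapply(ukey, function(k2) {
    rowMeans(data[, key == k2, drop = FALSE])
  }, numeric(nrow(data)))
  out <- matrix(out, nrow = nrow(data))
  colnames(out) <- paste0(
    "[", vapply(ukey, function(k2) {
      paste(paste0(design$names[factors], "=",
                   strsplit(k2, ",")[[1]]), collapse = ",")
    }, character(1)), "]")
  out
}

#' One-way ANOVA of a between-subject factor on subject means
#'
#' The main effect of a categorical between-subject factor is reported as a
#' plain one-way ANOVA on each subject's mean over all cells (the
#' within-subject structure is irrelevant to a between main effect).
#'
#' @param data Subjects x cells data matrix.
#' @param group Per-subject group labels.
#' @return List with `F`, `df_model`, `df_error`, `p`, `partial_eta2`.
#' @export
test_group_main <- function(data, group) {
  data <- as_data_matrix(data)
  m <- rowMeans(data)
  f <- droplevels(as.factor(group))
  k <- nlevels(f)
  n <- length(m)
  gm <- tapply(m, f, mean)
  ssb <- sum(table(f) * (gm - mean(m))^2)
  ssw <- sum((m - gm[as.integer(f)])^2)
  Fv <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = Fv, df_model = k - 1, df_error = n - k,
       p = stats::pf(Fv, k - 1, n - k, lower.tail = FALSE),
       partial_eta2 = ssb / (ssb + ssw))
}
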