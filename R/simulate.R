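#' Generate null data with controllable between-condition dependency
#'
#' Draws a subjects x cells matrix of standard-normal scores in which no
#' true effect of any kind exists, then induces correlation between
#' conditions: a uniformly random selection of half the columns
#' (`floor(cells / 2)`, without replacement) is each replaced by the
#' weighted sum of `(1 - dep)` times itself and `dep` times the row-wise
#' mean of all other columns. All replacements use the pre-mixing values
#' (simultaneous update), so the result does not depend on column order.
#' `dep = 0` leaves the matrix iid; `dep = 1` makes each selected column
#' exactly the mean of the others. Optional categorical group labels are
#' assigned per subject as `floor(k * uniform(0, 1)) + 1` (random,
#' generally unbalanced, group sizes), and an optional continuous
#' between-subject covariate is drawn standard normal.
#'
#' @param n_subjects Number of subjects (rows).
#' @param within_levels Level counts of the within-subject factors.
#' @param dep Dependency factor in \[0, 1\].
#' @param between_levels Optional level counts of categorical
#'   between-subject factors; one label vector is generated per factor.
#' @param include_cv Draw a standard-normal covariate per subject.
#' @param balanced_groups Assign groups by cycling instead of the uniform
#'   draw (exact balance up to rounding); useful for tests, not the default.
#' @return List with `data` (matrix), `groups` (list of factor vectors, or
#'   empty), and `cv` (numeric vector or `NULL`).
#' @export
simulate_null_data <- function(n_subjects, within_levels, dep = 0,
                               between_levels = NULL, include_cv = FALSE,
                               balanced_groups = FALSE) {
  stopifnot(dep >= 0, dep <= 1, n_subjects >= 2)
  cells <- prod(within_levels)
  X <- matrix(stats::rnorm(n_subjects * cells), n_subjects, cells)
  n_mix <- floor(cells / 2)
  if (n_mix >= 1L && dep > 0) {
    sel <- sample.int(cells, n_mix)
    pre <- X
    for (j in sel) {
      other_mean <- rowMeans(pre[, -j, drop = FALSE])
      X[, j] <- (1 - dep) * pre[, j] + dep * other_mean
    }
  } else if (n_mix >= 1L) {
    sel <- sample.int(cells, n_mix)  # consume the draw so dep=0 streams align
  }
  groups <- list()
  if (!is.null(between_levels)) {
    for (k in between_levels) {
      lab <- if (balanced_groups) rep_len(seq_len(k), n_subjects)
             else floor(k * stats::runif(n_subjects)) + 1L
      groups[[length(groups) + 1L]] <- factor(lab, levels = seq_len(k))
    }
  }
  cv <- if (include_cv) stats::rnorm(n_subjects) else NULL
  list(data = X, groups = groups, cv = cv)
}

#' False-positive-rate study over a grid of dependency factors
#'
#' Monte-Carlo verification that the parametric tests control the type-I
#' error rate when conditions are correlated. For each dependency factor in
#' `dep_grid`, `iterations` null datasets are generated with
#' [simulate_null_data()] and every effect type the method defines is
#' tested: each within-subject main effect and interaction, each group
#' factor's interaction with each within effect, and the covariate's
#' interaction with each within effect. The proportion of p-values below
#' `alpha` (the empirical false-positive rate) and the mean p-value are
#' recorded per (dep, effect) pair.
#'
#' @param within_levels Level counts of the within-subject factors.
#' @param between_levels Optional level counts of the group factors.
#' @param include_cv Include a continuous covariate and its interactions.
#' @param n_subjects Subjects per simulated dataset.
#' @param dep_grid Dependency factors to scan (default 0 to 1 in steps of 0.1).
#' @param iterations Null datasets per dependency factor.
#' @param alpha Nominal level. Default 0.05.
#' @param seed Optional integer seed.
#' @return Data frame of class `rm_fpr_table`: one row per (dep, effect)
#'   with `dep`, `effect`, `empirical_rate`, `mean_p`, `iterations`.
#' @export
fpr_study <- function(within_levels, between_levels = NULL,
                      include_cv = FALSE, n_subjects = 36,
                      dep_grid = seq(0, 1, by = 0.1),
                      iterations = 2000L, alpha = 0.05, seed = NULL) {
  iterations <- as.integer(iterations)
  stopifnot(iterations >= 1L)
  if (!is.null(seed)) set.seed(seed)
  design <- rm_design(within_levels)
  effects <- enumerate_effects(design)
  wnames <- names(effects)
  enames <- wnames
  if (!is.null(between_levels))
    for (b in seq_along(between_levels))
      enames <- c(enames, paste0("G", b, " x ", wnames))
  if (include_cv)
    enames <- c(enames, paste0("cv x ", wnames))
  rows <- list()
  for (dep in dep_grid) {
    hits <- stats::setNames(numeric(length(enames)), enames)
    psum <- stats::setNames(numeric(length(enames)), enames)
    valid <- stats::setNames(numeric(length(enames)), enames)
    for (it in seq_len(iterations)) {
      sim <- simulate_null_data(n_subjects, within_levels, dep = dep,
                                between_levels = between_levels,
                                include_cv = include_cv)
      for (w in seq_along(effects)) {
        p <- test_within_effect(sim$data, effects[[w]])$p
        nm <- wnames[w]
        hits[nm] <- hits[nm] + (p < alpha); psum[nm] <- psum[nm] + p
        valid[nm] <- valid[nm] + 1
      }
      if (length(sim$groups)) {
        for (b in seq_along(sim$groups)) {
          g <- droplevels(sim$groups[[b]])
          if (nlevels(g) < 2L) next  # degenerate draw: all one group
          gc <- suppressWarnings(group_coding(g))
          for (w in seq_along(effects)) {
            p <- test_within_by_group(sim$data, effects[[w]], gc)$p
            nm <- paste0("G", b, " x ", wnames[w])
            hits[nm] <- hits[nm] + (p < alpha); psum[nm] <- psum[nm] + p
            valid[nm] <- valid[nm] + 1
          }
        }
      }
      if (!is.null(sim$cv)) {
        for (w in seq_along(effects)) {
          p <- test_within_by_cv(sim$data, effects[[w]], sim$cv)$p
          nm <- paste0("cv x ", wnames[w])
          hits[nm] <- hits[nm] + (p < alpha); psum[nm] <- psum[nm] + p
          valid[nm] <- valid[nm] + 1
        }
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      dep = dep, effect = enames,
      empirical_rate = as.numeric(hits / valid),
      mean_p = as.numeric(psum / valid),
      iterations = as.integer(valid),
      row.names = NULL
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rm_fpr_table", class(out))
  out
}

#' @export
print.rm_fpr_table <- function(x, ...) {
  cat("Null-simulation false-positive rates (alpha-level rejections)\n")
  worst <- x[which.max(x$empirical_rate), ]
  NextMethod()
  cat(sprintf("Worst case: %.4f (%s at dep = %s)\n",
              worst$empirical_rate, worst$effect, format(worst$dep)))
  invisible(x)
}
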