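#' Repeated-measures ANOVA for an N-way within-subject design
#'
#' Fits the full effect-wise repeated-measures analysis: every
#' within-subject main effect and interaction is tested by its own stacked
#' regression on the effect's reduced data matrix, with Greenhouse-Geisser
#' df correction for multi-contrast effects and partial eta squared as the
#' effect size. If categorical between-subject factors are supplied, their
#' main effect (one-way ANOVA on subject means) and their interaction with
#' every within-subject effect are tested; a continuous covariate adds its
#' interaction with every within-subject effect plus descriptive
#' correlation follow-ups. Because every test is constructed independently,
#' adding between-subject terms never changes any within-subject result.
#'
#' When `perm_iterations` is set, non-parametric p-values are added:
#' per-participant sign-flip randomization for within-subject effects and
#' covariate permutation for covariate interactions.
#'
#' Within-subject interactions with p below `alpha` are unpacked into
#' recursive simple-effect tests and uncorrected pairwise paired t-tests
#' (see [unpack_interaction()] and [pairwise_tests()]); unpacking trees are
#' attached for all interactions and flagged `protected` when the parent
#' interaction is significant.
#'
#' @param data Numeric matrix or data frame: one row per subject, one
#'   column per design cell, with later within-subject factors nested
#'   inside earlier ones (first factor varies slowest over columns). Rows
#'   containing missing values are dropped with a warning.
#' @param within Named vector of level counts, e.g. `c(task = 2, load = 3)`.
#' @param between Optional list (or single vector) of per-subject group
#'   labels, one element per categorical between-subject factor.
#' @param cv Optional list (or single numeric vector) of per-subject
#'   continuous covariates.
#' @param alpha Significance level gating interaction unpacking and the
#'   `protected` flag. Default 0.05.
#' @param perm_iterations If non-`NULL`, number of randomization/permutation
#'   iterations for non-parametric p-values.
#' @param seed Optional integer seed used for the permutation machinery.
#' @return An object of class `rm_anova`: list with `design`, the per-term
#'   `effects` table (term, type, F, dfs, epsilon, p, p_perm, partial
#'   eta squared, sums of squares), `tests` (the underlying
#'   `rm_effect_test` objects), `unpacking` (named list of
#'   `rm_unpack_node` trees with pairwise tables), `cv_followups`,
#'   `n_subjects`, `alpha`, and `seed`.
#' @examples
#' set.seed(42)
#' dat <- matrix(rnorm(20 * 6), 20, 6)
#' dat[, 4:6] <- dat[, 4:6] + 0.8  # main effect of the 2-level factor
#' fit <- rm_anova(dat, within = c(task = 2, load = 3))
#' fit
#' @export
rm_anova <- function(data, within, between = NULL, cv = NULL,
                     alpha = 0.05, perm_iterations = NULL, seed = NULL) {
  design <- as_rm_design(within)
  data <- as_data_matrix(data)
  if (ncol(data) != design$n_cells)
    stop("data has ", ncol(data), " cell columns but the design implies ",
         design$n_cells, call. = FALSE)
  keepers <- !apply(data, 1L, anyNA)
  if (!all(keepers)) {
    warning("dropping ", sum(!keepers), " row(s) with missing values")
    data <- data[keepers, , drop = FALSE]
    between <- lapply(wrap_list(between), function(b) b[keepers])
    cv <- lapply(wrap_list(cv), function(v) v[keepers])
  }
  between <- wrap_list(between)
  cv <- wrap_list(cv)
  n <- nrow(data)
  if (n < 2L) stop("at least 2 complete subjects required", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  effects <- enumerate_effects(design)
  tests <- list()
  rows <- list()
  add_row <- function(term, type, r) {
    rows[[length(rows) + 1L]] <<- data.frame(
      term = term, type = type, F = r$F,
      df_model = as.numeric(r$df_model),
      df_error = as.numeric(r$df_error),
      epsilon = if (is.null(r$epsilon)) NA_real_ else r$epsilon,
      p = r$p,
      p_perm = if (is.null(r$p_perm)) NA_real_ else r$p_perm,
      partial_eta2 = r$partial_eta2,
      ss_model = if (is.null(r$ss_model)) NA_real_ else r$ss_model,
      ss_error = if (is.null(r$ss_error)) NA_real_ else r$ss_error,
      row.names = NULL)
  }

  for (nm in names(effects)) {
    r <- test_within_effect(data, effects[[nm]])
    if (!is.null(perm_iterations)) {
      r$p_perm <- signflip_test(data, effects[[nm]],
                                iterations = perm_iterations)$p_perm
      if (r$p_perm == 0)
        message("permutation p = 0 for ", nm,
                " (observed F exceeded all ", perm_iterations,
                " null draws)")
    }
    tests[[nm]] <- r
    add_row(nm, "within", r)
  }

  if (length(between)) {
    bnames <- names(between)
    if (is.null(bnames)) bnames <- paste0("G", seq_along(between))
    for (b in seq_along(between)) {
      gmain <- test_group_main(data, between[[b]])
      add_row(bnames[b], "between", gmain)
      gc <- group_coding(between[[b]])
      for (nm in names(effects)) {
        r <- test_within_by_group(data, effects[[nm]], gc)
        key <- paste0(bnames[b], " x ", nm)
        tests[[key]] <- r
        add_row(key, "group_x_within", r)
      }
    }
  }

  followups <- list()
  if (length(cv)) {
    cnames <- names(cv)
    if (is.null(cnames)) cnames <- paste0("cv", seq_along(cv))
    for (v in seq_along(cv)) {
      for (nm in names(effects)) {
        r <- test_within_by_cv(data, effects[[nm]], cv[[v]])
        if (!is.null(perm_iterations))
          r$p_perm <- cv_permutation_test(data, effects[[nm]], cv[[v]],
                                          iterations = perm_iterations)$p_perm
        key <- paste0(cnames[v], " x ", nm)
        tests[[key]] <- r
        add_row(key, "cv_x_within", r)
        followups[[key]] <- cv_followups(data, design,
                                         effects[[nm]]$factors, cv[[v]])
      }
    }
  }

  unpacking <- list()
  for (nm in names(effects)) {
    if (length(effects[[nm]]$factors) < 2L) next
    tree <- unpack_interaction(data, design, effects[[nm]]$factors)
    unpacking[[nm]] <- list(
      tree = tree,
      pairwise = pairwise_tests(data, design, effects[[nm]]$factors),
      protected = tests[[nm]]$p < alpha
    )
  }

  structure(
    list(design = design,
         effects = do.call(rbind, rows),
         tests = tests,
         unpacking = unpacking,
         cv_followups = followups,
         n_subjects = n, alpha = alpha, seed = seed),
    class = "rm_anova")
}

wrap_list <- function(x) {
  if (is.null(x)) list()
  else if (is.list(x) && !is.data.frame(x)) x
  else if (is.data.frame(x)) as.list(x)
  else list(x)
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (effect coding), n =", x$n_subjects,
      "subjects\n")
  print(x$design)
  cat("\n")
  tab <- x$effects
  disp <- data.frame(
    term = tab$term,
    F = formatC(tab$F, digits = 3, format = "f"),
    df = sprintf("(%s, %s)",
                 format(ifelse(is.na(tab$epsilon), tab$df_model,
                               tab$epsilon * tab$df_model), digits = 4),
                 format(ifelse(is.na(tab$epsilon), tab$df_error,
                               tab$epsilon * tab$df_error), digits = 4)),
    epsilon = ifelse(is.na(tab$epsilon), "",
                     formatC(tab$epsilon, digits = 3, format = "f")),
    p = format_p(tab$p),
    p_perm = ifelse(is.na(tab$p_perm), "", format_p(tab$p_perm)),
    pes = formatC(tab$partial_eta2, digits = 3, format = "f"))
  names(disp)[7] <- "partial_eta2"
  print(disp, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' @export
summary.rm_anova <- function(object, ...) {
  structure(object, class = c("summary.rm_anova", "rm_anova"))
}

#' @export
print.summary.rm_anova <- function(x, ...) {
  NextMethod()
  if (length(x$unpacking)) {
    for (nm in names(x$unpacking)) {
      u <- x$unpacking[[nm]]
      if (!isTRUE(u$protected)) next
      cat("\nUnpacking of significant interaction ", nm,
          " (uncorrected simple effects):\n", sep = "")
      print(u$tree)
      cat("Pairwise paired t-tests (uncorrected):\n")
      pw <- u$pairwise
      pw$p <- format_p(pw$p)
      pw$mean_diff <- formatC(pw$mean_diff, digits = 3, format = "f")
      pw$t <- formatC(pw$t, digits = 3, format = "f")
      print(pw, row.names = FALSE)
    }
  }
  if (length(x$cv_followups)) {
    sig <- x$effects$term[x$effects$type == "cv_x_within" &
                            x$effects$p < x$alpha]
    for (nm in intersect(names(x$cv_followups), sig)) {
      cat("\nCorrelation follow-ups for ", nm, ":\n", sep = "")
      fu <- x$cv_followups[[nm]]
      fu$r <- formatC(fu$r, digits = 3, format = "f")
      fu$p <- format_p(fu$p)
      print(fu, row.names = FALSE)
    }
  }
  invisible(x)
}

#' @export
as.data.frame.rm_anova <- function(x, ...) x$effects

#' Read a wide-format repeated-measures CSV
#'
#' Reads a CSV with one row per subject. Columns named in `between` and
#' `cv` are extracted as group factors and covariates; all remaining
#' columns, in file order, are taken as the design cells and validated
#' against the design's cell count. Rows with any missing value are dropped
#' with a warning (listwise deletion).
#'
#' @param path Path to a CSV file with a header row.
#' @param within Named vector of within-subject level counts.
#' @param between Character vector of group-factor column names.
#' @param cv Character vector of covariate column names.
#' @return List with `data` (subjects x cells matrix), `between` (named
#'   list of factors), and `cv` (named list of numeric vectors), ready for
#'   [rm_anova()].
#' @export
read_rm_csv <- function(path, within, between = character(0),
                        cv = character(0)) {
  design <- as_rm_design(within)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  missing_cols <- setdiff(c(between, cv), names(df))
  if (length(missing_cols))
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  cell_cols <- setdiff(names(df), c(between, cv))
  if (length(cell_cols) != design$n_cells)
    stop("expected ", design$n_cells, " cell columns but found ",
         length(cell_cols), call. = FALSE)
  for (cc in c(cell_cols, cv)) {
    if (!is.numeric(df[[cc]]))
      stop("non-numeric values in column '", cc, "'", call. = FALSE)
  }
  complete <- stats::complete.cases(df[, c(cell_cols, between, cv),
                                       drop = FALSE])
  if (!all(complete)) {
    warning("dropping ", sum(!complete), " row(s) with missing values")
    df <- df[complete, , drop = FALSE]
  }
  list(
    data = as.matrix(df[, cell_cols, drop = FALSE]),
    between = stats::setNames(lapply(between, function(b) factor(df[[b]])),
                              between),
    cv = stats::setNames(lapply(cv, function(v) as.numeric(df[[v]])), cv)
  )
}
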