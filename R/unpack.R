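#' Recursively unpack an interaction into simple effects
#'
#' Descriptive follow-up of a significant k-way within-subject interaction:
#' for each level of the last involved factor (the one with the highest
#' design index), the data are sliced to that level's cells and the
#' (k-1)-way interaction among the remaining involved factors is tested;
#' recursion continues until a single factor is tested at a fully specified
#' combination of the other involved factors' levels. Tests are uncorrected
#' for multiplicity — they are protected by the significant parent
#' interaction and serve a descriptive purpose.
#'
#' @param data Subjects x cells data matrix.
#' @param design `rm_design` (or level-count vector) describing the columns.
#' @param factors Indices of the involved factors (>= 2 of them).
#' @return An `rm_unpack_node`: list with `fixed_levels` (named integer
#'   vector of factor levels held constant), `factors` (tested subset),
#'   `result` (an `rm_effect_test`), and `children` (list of nodes, empty
#'   at single-factor leaves).
#' @export
unpack_interaction <- function(data, design, factors) {
  design <- as_rm_design(design)
  factors <- sort(as.integer(factors))
  if (length(factors) < 2L)
    stop("nothing to unpack: effect involves a single factor", call. = FALSE)
  data <- as_data_matrix(data)
  unpack_node(data, design$levels, design$names, factors, fixed = integer(0))
}

unpack_node <- function(data, levels, names, factors, fixed) {
  ct <- enumerate_cells(stats::setNames(levels, names))
  coding <- if (length(factors) == 1L) main_effect_coding(ct, factors)
            else interaction_coding(ct, factors)
  node <- list(
    fixed_levels = fixed,
    factors = stats::setNames(factors, names[factors]),
    result = test_within_effect(data, coding),
    children = list()
  )
  if (length(factors) >= 2L) {
    last <- max(factors)
    rest <- setdiff(factors, last)
    for (l in seq_len(levels[last])) {
      keep <- ct[last, ] == l
      sub_data <- data[, keep, drop = FALSE]
      # dropping factor `last` from the design; indices above it shift down
      sub_levels <- levels[-last]
      sub_names <- names[-last]
      sub_factors <- ifelse(rest > last, rest - 1L, rest)
      child <- unpack_node(sub_data, sub_levels, sub_names, sub_factors,
                           fixed = c(fixed,
                                     stats::setNames(l, names[last])))
      node$children[[length(node$children) + 1L]] <- child
    }
  }
  class(node) <- "rm_unpack_node"
  node
}

#' @export
print.rm_unpack_node <- function(x, indent = 0L, ...) {
  pad <- strrep("  ", indent)
  where <- if (length(x$fixed_levels))
    paste0(" @ ", paste(names(x$fixed_levels), "=", x$fixed_levels,
                        collapse = ", "))
  else ""
  r <- x$result
  cat(sprintf("%s%s%s: F(%s, %s) = %s, p = %s\n",
              pad, paste(names(x$factors), collapse = ":"), where,
              format(r$epsilon * r$df_model, digits = 4),
              format(r$epsilon * r$df_error, digits = 4),
              format(r$F, digits = 4), format_p(r$p)))
  for (ch in x$children) print(ch, indent = indent + 1L)
  invisible(x)
}

#' Pairwise paired t-tests among an effect's conditions
#'
#' The second follow-up for a significant interaction (or main effect):
#' per-subject means are computed for every condition spanned by the
#' effect's factors (marginalizing over uninvolved factors), and each
#' unordered pair of conditions is compared with a two-sided paired t-test
#' on `n - 1` degrees of freedom. P-values are deliberately uncorrected.
#'
#' @param data Subjects x cells data matrix.
#' @param design `rm_design` (or level-count vector).
#' @param factors Indices of the involved factors.
#' @return Data frame with one row per condition pair: `cell_a`, `cell_b`,
#'   `mean_diff`, `t`, `df`, `p`.
#' @export
pairwise_tests <- function(data, design, factors) {
  data <- as_data_matrix(data)
  cells <- effect_cell_means(data, design, factors)
  labs <- colnames(cells)
  m <- ncol(cells)
  if (m < 2L) stop("effect spans fewer than 2 conditions", call. = FALSE)
  n <- nrow(cells)
  prs <- utils::combn(m, 2L)
  out <- vector("list", ncol(prs))
  for (i in seq_len(ncol(prs))) {
    a <- prs[1L, i]; b <- prs[2L, i]
    d <- cells[, a] - cells[, b]
    md <- mean(d)
    sdd <- stats::sd(d)
    if (sdd == 0) {
      tv <- if (md == 0) 0 else Inf * sign(md)
      p <- if (md == 0) 1 else 0
    } else {
      tv <- md / (sdd / sqrt(n))
      p <- 2 * stats::pt(abs(tv), n - 1, lower.tail = FALSE)
    }
    out[[i]] <- data.frame(cell_a = labs[a], cell_b = labs[b],
                           mean_diff = md, t = tv, df = n - 1, p = p)
  }
  do.call(rbind, out)
}
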