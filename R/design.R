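#' Describe a within-subject factorial design
#'
#' A design is an ordered set of within-subject factors, each with a number
#' of levels. The ordering matters: the columns of a data matrix analysed
#' under the design must nest later factors within earlier ones, i.e. the
#' first factor varies slowest across columns and the last factor fastest.
#'
#' @param within Named (or unnamed) integer vector of level counts, one per
#'   within-subject factor, in nesting order. Every factor needs at least
#'   two levels. Unnamed factors are labelled `W1`, `W2`, ...
#' @return An object of class `rm_design` with elements `levels`, `names`,
#'   and `n_cells` (the product of the level counts).
#' @examples
#' d <- rm_design(c(task = 2, load = 3))
#' d$n_cells  # 6
#' @export
rm_design <- function(within) {
  levels <- as.integer(within)
  if (length(levels) < 1L)
    stop("a design needs at least one within-subject factor", call. = FALSE)
  if (any(is.na(levels)) || any(levels < 2L))
    stop("every within-subject factor needs at least 2 levels", call. = FALSE)
  nms <- names(within)
  if (is.null(nms) || any(!nzchar(nms)))
    nms <- paste0("W", seq_along(levels))
  if (anyDuplicated(nms))
    stop("factor names must be unique", call. = FALSE)
  structure(
    list(levels = levels, names = nms, n_cells = prod(levels)),
    class = "rm_design"
  )
}

#' @export
print.rm_design <- function(x, ...) {
  cat("Within-subject design: ",
      paste(paste0(x$names, "(", x$levels, ")"), collapse = " x "),
      " — ", x$n_cells, " cells\n", sep = "")
  invisible(x)
}

#' Enumerate the design cells (combinations-matrix)
#'
#' Builds the combinations-matrix of a factorial design: one column per
#' design cell, one row per factor, holding the 1-based level index of that
#' factor in that cell. Columns follow the nesting convention — the first
#' factor varies slowest, the last fastest — so column `j` of the
#' combinations-matrix describes column `j` of a conforming data matrix.
#'
#' @param design An [rm_design] object, or a bare vector of level counts.
#' @return Integer matrix, `length(levels)` rows by `prod(levels)` columns.
#' @examples
#' enumerate_cells(c(2, 3))
#' # [1 1 1 2 2 2]
#' # [1 2 3 1 2 3]
#' @export
enumerate_cells <- function(design) {
  design <- as_rm_design(design)
  lv <- design$levels
  n <- length(lv)
  cells <- matrix(0L, nrow = n, ncol = design$n_cells)
  for (f in seq_len(n)) {
    each  <- if (f < n) prod(lv[(f + 1L):n]) else 1L
    times <- if (f > 1L) prod(lv[seq_len(f - 1L)]) else 1L
    cells[f, ] <- rep(rep(seq_len(lv[f]), each = each), times = times)
  }
  rownames(cells) <- design$names
  cells
}

as_rm_design <- function(design) {
  if (inherits(design, "rm_design")) design else rm_design(design)
}

#' Effect coding for one main effect
#'
#' For a factor with L levels, builds the L-1 column effect-coding matrix
#' over design cells: for each level n after the first there is one contrast
#' column in which cells at level 1 of the factor are coded -1, cells at
#' level n are coded +1, and all other cells 0. Every column sums to zero
#' over cells; together the columns span all linear contrasts among the
#' factor's levels.
#'
#' @param cell_table Combinations-matrix from [enumerate_cells()].
#' @param factor Index of the factor (row of `cell_table`) to code.
#' @return An `effect_coding` object: list with `factors` (the involved
#'   factor indices), `matrix` (cells x contrasts, values in -1/0/1), and
#'   `labels` (one per contrast column).
#' @examples
#' ct <- enumerate_cells(c(2, 3))
#' main_effect_coding(ct, 1)$matrix  # single column: -1 -1 -1 1 1 1
#' main_effect_coding(ct, 2)$matrix  # two columns
#' @export
main_effect_coding <- function(cell_table, factor) {
  stopifnot(is.matrix(cell_table))
  factor <- as.integer(factor)
  if (factor < 1L || factor > nrow(cell_table))
    stop("factor index out of range", call. = FALSE)
  lev <- cell_table[factor, ]
  L <- max(lev)
  m <- vapply(2:L, function(n) {
    col <- integer(length(lev))
    col[lev == 1L] <- -1L
    col[lev == n] <- 1L
    col
  }, integer(length(lev)))
  m <- matrix(m, nrow = length(lev))
  nm <- rownames(cell_table)[factor]
  if (is.null(nm)) nm <- paste0("W", factor)
  new_effect_coding(
    factors = factor,
    matrix = m,
    labels = paste0(nm, ":", 2:L, "-1")
  )
}

new_effect_coding <- function(factors, matrix, labels) {
  structure(list(factors = factors, matrix = matrix, labels = labels),
            class = "effect_coding")
}

#' @export
print.effect_coding <- function(x, ...) {
  cat("Effect coding for factor set {", paste(x$factors, collapse = ","),
      "}: ", nrow(x$matrix), " cells x ", ncol(x$matrix), " contrast(s)\n",
      sep = "")
  m <- x$matrix
  colnames(m) <- x$labels
  print(m)
  invisible(x)
}

#' Effect coding for an interaction
#'
#' The coding matrix of a k-way interaction contains one column for every
#' combination of contrast vectors of the involved factors' main-effect
#' codings; each column is the elementwise product of the chosen contrast
#' columns. Combinations are enumerated with the last involved factor's
#' contrast index varying fastest, mirroring the cell nesting convention.
#'
#' @param cell_table Combinations-matrix from [enumerate_cells()].
#' @param factor_subset Two or more distinct factor indices, ascending.
#' @return An `effect_coding` object with
#'   `prod(levels[factor_subset] - 1)` columns.
#' @examples
#' ct <- enumerate_cells(c(2, 3))
#' interaction_coding(ct, c(1, 2))$matrix
#' @export
interaction_coding <- function(cell_table, factor_subset) {
  factor_subset <- as.integer(factor_subset)
  if (length(factor_subset) < 2L)
    stop("an interaction involves at least 2 factors; use main_effect_coding",
         call. = FALSE)
  if (anyDuplicated(factor_subset) || is.unsorted(factor_subset, strictly = TRUE))
    stop("factor_subset must be distinct ascending indices", call. = FALSE)
  mains <- lapply(factor_subset, function(f) main_effect_coding(cell_table, f))
  q <- vapply(mains, function(e) ncol(e$matrix), integer(1))
  k <- length(q)
  n_cols <- prod(q)
  n_cells <- ncol(cell_table)
  # contrast-index combinations, last factor fastest (same pattern as cells)
  m <- matrix(1, nrow = n_cells, ncol = n_cols)
  labels <- rep("", n_cols)
  idx <- matrix(0L, nrow = k, ncol = n_cols)
  for (i in seq_len(k)) {
    each  <- if (i < k) prod(q[(i + 1L):k]) else 1L
    times <- if (i > 1L) prod(q[seq_len(i - 1L)]) else 1L
    idx[i, ] <- rep(rep(seq_len(q[i]), each = each), times = times)
  }
  for (j in seq_len(n_cols)) {
    col <- rep(1, n_cells)
    lab <- character(k)
    for (i in seq_len(k)) {
      col <- col * mains[[i]]$matrix[, idx[i, j]]
      lab[i] <- mains[[i]]$labels[idx[i, j]]
    }
    m[, j] <- col
    labels[j] <- paste(lab, collapse = " x ")
  }
  new_effect_coding(factors = factor_subset, matrix = m, labels = labels)
}

#' Enumerate all testable effects of a design
#'
#' Produces the effect coding for every main effect and every k-way
#' interaction, k = 2..N, of an N-factor design: 2^N - 1 effects in all.
#' Order is deterministic: all main effects first, then all 2-way
#' interactions, then 3-way, and so on, lexicographically within each block.
#' Jointly the coding columns decompose the full between-cell degrees of
#' freedom: their column counts sum to `prod(levels) - 1`.
#'
#' @param design An [rm_design] object or vector of level counts.
#' @return Named list of `effect_coding` objects.
#' @examples
#' length(enumerate_effects(c(2, 3)))  # 3: two mains + one interaction
#' @export
enumerate_effects <- function(design) {
  design <- as_rm_design(design)
  ct <- enumerate_cells(design)
  n <- length(design$levels)
  out <- list()
  for (k in seq_len(n)) {
    subsets <- utils::combn(n, k, simplify = FALSE)
    for (s in subsets) {
      eff <- if (k == 1L) main_effect_coding(ct, s) else interaction_coding(ct, s)
      out[[paste(design$names[s], collapse = ":")]] <- eff
    }
  }
  out
}
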