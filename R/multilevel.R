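#' Two-factor within-subject variance decomposition
#'
#' Splits a repeated-measures data matrix into within- and between-cell
#' components, where a cell is a (subject, diet period) pair: each subject's
#' series is cut at the diet switch, so the within part removes subject-and-
#' period means and retains only the perturbation-driven variation around
#' them. The between-subject factor (treatment arm) is absorbed into the
#' between part, since treatment never varies within a subject. Responses
#' should be decomposed with the identical operator (same labels).
#'
#' @param X numeric matrix, samples x variables.
#' @param subjects subject id per sample (row).
#' @param diet diet label per sample (e.g. NC/HFD); defines the period cut.
#'   Pass a single constant to collapse to plain subject-level centering.
#' @param treatment optional treatment label per sample (kept for the cell
#'   key report; it is constant within subject and does not change cells).
#' @return object of class \code{ml_decomposition}: \code{within} and
#'   \code{between} matrices summing to the grand-mean-centered input,
#'   \code{cell_key} per-sample cell labels, and \code{singleton} flags for
#'   samples whose cell has a single observation (their within row is zero).
#' @export
within_subject_split <- function(X, subjects, diet = NULL, treatment = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(subjects) != n) stop("subjects must have one label per row")
  if (is.null(diet)) diet <- rep("all", n)
  if (length(diet) != n) stop("diet must have one label per row")
  cell <- interaction(subjects, diet, drop = TRUE, lex.order = TRUE)
  cm <- rowsum(X, cell) / as.vector(table(cell))
  cell_mean <- cm[as.character(cell), , drop = FALSE]
  grand <- colMeans(X)
  within <- X - cell_mean
  between <- sweep(cell_mean, 2L, grand)
  singleton <- as.vector(table(cell)[as.character(cell)]) == 1L
  if (any(singleton)) {
    warning(sum(singleton), " sample(s) in singleton (subject x period) ",
            "cells contribute no within-cell variation")
  }
  dimnames(within) <- dimnames(between) <- dimnames(X)
  structure(list(within = within, between = between,
                 cell_key = data.frame(sample = seq_len(n),
                                       subject = as.character(subjects),
                                       cell = as.character(cell),
                                       treatment = if (is.null(treatment))
                                         NA_character_ else as.character(treatment)),
                 singleton = singleton),
            class = "ml_decomposition")
}

#' @export
print.ml_decomposition <- function(x, ...) {
  cat(sprintf("ml_decomposition: %d samples x %d variables, %d cells\n",
              nrow(x$within), ncol(x$within),
              length(unique(x$cell_key$cell))))
  invisible(x)
}
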