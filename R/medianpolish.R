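#' Two-way median polish with missing-cell support
#'
#' Iterative alternating subtraction of row and column medians (rows
#' first), decomposing a grid into overall + row effects + column effects
#' + residuals. Missing cells are ignored in every median and remain
#' missing in the residuals; an all-missing row or column gets a zero
#' effect with a warning (its fitted value falls back to the overall term
#' plus the orthogonal effect). After each pair of sweeps the medians of
#' the effect vectors over fitted rows/columns are folded into the
#' overall term, so at convergence the row- and column-effect medians are
#' (numerically) zero and the overall term sits at the grand median of
#' the fitted cells.
#'
#' A sweep is considered converged when its total absolute median change
#' falls below \code{tol} times the robust scale of the input (median
#' absolute deviation from the grid median, floored at 1 for degenerate
#' grids). Convergence of median polish is geometric rather than exact
#' and occasional long plateaus occur on even-dimension grids, so tight
#' agreement with an independently converged fit requires a small
#' \code{tol} and a generous \code{maxIter}; the sweep loop is compiled,
#' so thousands of sweeps are cheap.
#'
#' @param x numeric matrix (NAs allowed) with at least 2 rows, 2 columns
#'   and one fitted cell in each.
#' @param maxIter maximum number of sweep pairs (default 20).
#' @param tol relative convergence tolerance (default 1e-6).
#' @return a \code{\linkS4class{MedianPolishFit}}.
#' @examples
#' fit <- medianPolish(matrix(c(1, 3, 2, 4), 2, 2))
#' fit@residuals      # exactly additive grid: all zero
#' @export
medianPolish <- function(x, maxIter = 20L, tol = 1e-6) {
  stopifnot(is.matrix(x), nrow(x) >= 2L, ncol(x) >= 2L)
  if (all(is.na(x))) stop("grid has no fitted cells")
  if (any(apply(x, 1, function(r) all(is.na(r)))) ||
      any(apply(x, 2, function(c) all(is.na(c)))))
    warning("all-missing row(s)/column(s): their effects are set to 0")
  scale0 <- stats::median(abs(x - stats::median(x, na.rm = TRUE)),
                          na.rm = TRUE)
  if (!is.finite(scale0) || scale0 == 0) scale0 <- 1
  res <- .polishSweeps(x, as.integer(maxIter), tol, scale0)
  resid <- res$residuals
  dimnames(resid) <- dimnames(x)
  new("MedianPolishFit", overall = res$overall,
      rowEffects = res$rowEffects, colEffects = res$colEffects,
      residuals = resid, nIter = res$nIter, converged = res$converged)
}
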