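# Shared statistics: Pearson chi-square on 2x2 contingency tables (no
# continuity correction, matching the large-count setting) and Student's
# paired t-test, both thin wrappers over stats with the degenerate cases
# made explicit.

#' Pearson chi-square test on a 2x2 contingency table
#'
#' No continuity correction is applied (configurable); with the large
#' counts typical of genome-wide contingency tables the correction is
#' immaterial.
#'
#' @param tbl 2x2 numeric matrix of non-negative counts.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with `statistic`, `df` (1), `p.value`.
#' @examples
#' chiSquare(matrix(c(5937, 2131, 3597, 981), 2))
#' @export
chiSquare <- function(tbl, correct = FALSE) {
  tbl <- as.matrix(tbl)
  if (!all(dim(tbl) == c(2, 2))) stop("need a 2x2 table")
  if (any(tbl < 0)) stop("counts must be non-negative")
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0))
    stop("zero row or column margin: chi-square undefined")
  ct <- stats::chisq.test(tbl, correct = correct)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value)
}

#' Student's paired t-test
#'
#' Paired t on the within-pair differences.  Degenerate inputs are
#' resolved explicitly: all differences zero gives t = 0, P = 1; constant
#' non-zero differences give P = 0 (below any floor).
#'
#' @param x,y numeric vectors of equal length >= 2; incomplete pairs are
#'   dropped.
#' @return list with `statistic`, `df`, `p.value`, `mean_difference`.
#' @export
pairedT <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need >= 2 complete pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(statistic = 0, df = n - 1, p.value = 1,
                  mean_difference = 0))
    return(list(statistic = sign(mean(d)) * Inf, df = n - 1, p.value = 0,
                mean_difference = mean(d)))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, mean_difference = unname(tt$estimate))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Convenience wrapper labelled as an extension: the primary report keeps
#' raw P-values, and q-values are appended only on request.
#'
#' @param p numeric vector of P-values.
#' @return adjusted values from [stats::p.adjust()] with `method = "BH"`.
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")
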