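# Horse-race expression dominance: per-tissue two-fold-or-greater calls on
# homoeolog pairs, category summaries, and paired mean-expression tests.

#' Horse-race dominance call for one homoeolog pair in one tissue
#'
#' The maize1 copy "wins the horse" in a tissue when its expression is
#' two-fold or greater than that of its maize2 homoeolog (ties at exactly
#' the fold threshold count as dominant), and symmetrically for maize2.
#' The winner must additionally reach `minExpr`, which guards against
#' degenerate calls on (0, 0) pairs.  Vectorised over pairs.
#'
#' @param fpkm1,fpkm2 non-negative expression (or protein-abundance)
#'   values of the maize1 and maize2 copies.
#' @param fold fold threshold (default 2).
#' @param minExpr minimum expression of the dominant member (default 1).
#' @return character vector: `"maize1_dominant"`, `"maize2_dominant"` or
#'   `"no_call"`.
#' @examples
#' classifyPair(c(10, 6, 0), c(4, 4, 0))
#' @export
classifyPair <- function(fpkm1, fpkm2, fold = 2.0, minExpr = 1.0) {
  if (any(fpkm1 < 0, na.rm = TRUE) || any(fpkm2 < 0, na.rm = TRUE))
    stop("expression values must be >= 0")
  out <- rep("no_call", length(fpkm1))
  out[fpkm1 >= fold * fpkm2 & fpkm1 >= minExpr] <- "maize1_dominant"
  out[fpkm2 >= fold * fpkm1 & fpkm2 >= minExpr] <- "maize2_dominant"
  out[is.na(fpkm1) | is.na(fpkm2)] <- "no_call"
  out
}

#' Per-tissue dominance percentages by category
#'
#' For every tissue and chromatin-environment category, the percentage of
#' pairs dominated by each subgenome (denominator: all pairs of the
#' category).  A headline summary averaged across tissues is attached.
#'
#' @param mat numeric matrix, rows = genes (rownames = ids), columns =
#'   tissues.
#' @param pairs data.frame with columns `m1_gene`, `m2_gene` and
#'   optionally `category`.
#' @param fold,minExpr passed to [classifyPair()].
#' @return list with `calls` (long table: pair, tissue, call, category),
#'   `per_tissue` (category x tissue percentages) and `summary`
#'   (tissue-averaged percentages per category).
#' @export
dominanceSummary <- function(mat, pairs, fold = 2.0, minExpr = 1.0) {
  pr <- as.data.table(pairs)
  if (!all(c("m1_gene", "m2_gene") %in% names(pr)))
    stop("'pairs' needs m1_gene and m2_gene columns")
  if (!"category" %in% names(pr)) pr[, category := "all"]
  miss <- setdiff(c(pr$m1_gene, pr$m2_gene), rownames(mat))
  if (length(miss))
    stop(length(miss), " pair gene(s) absent from the matrix")
  tissues <- colnames(mat)
  calls <- rbindlist(lapply(tissues, function(tt) {
    data.table(pair = seq_len(nrow(pr)), tissue = tt,
               category = pr$category,
               call = classifyPair(mat[pr$m1_gene, tt], mat[pr$m2_gene, tt],
                                   fold = fold, minExpr = minExpr))
  }))
  per <- calls[, {
    n <- .N
    list(pct_maize1 = 100 * sum(call == "maize1_dominant") / n,
         pct_maize2 = 100 * sum(call == "maize2_dominant") / n,
         pct_no_call = 100 * sum(call == "no_call") / n,
         n_pairs = n)
  }, by = .(category, tissue)]
  summ <- per[, .(pct_maize1 = mean(pct_maize1),
                  pct_maize2 = mean(pct_maize2),
                  pct_no_call = mean(pct_no_call),
                  gap = mean(pct_maize1) - mean(pct_maize2)),
              by = category]
  list(calls = calls[], per_tissue = per[], summary = summ[])
}

#' Paired comparison of mean homoeolog expression
#'
#' Per pair, the mean expression across tissues of each copy; the two
#' sides are then compared with a paired Student's t-test, on the raw
#' scale and optionally on log2(x + 1).
#'
#' @param mat expression matrix (rows = genes, columns = tissues).
#' @param pairs data.frame with columns `m1_gene`, `m2_gene`.
#' @param log2scale also test on the log2(x+1) scale (default TRUE).
#' @return list with `mean_m1`, `mean_m2`, `difference`, `t`, `df`, `p`
#'   and, when requested, `p_log2`.
#' @export
meanExpressionCompare <- function(mat, pairs, log2scale = TRUE) {
  pr <- as.data.table(pairs)
  if (nrow(pr) < 2) stop("need >= 2 pairs for a paired comparison")
  x <- rowMeans(mat[pr$m1_gene, , drop = FALSE])
  y <- rowMeans(mat[pr$m2_gene, , drop = FALSE])
  tt <- pairedT(x, y)
  out <- list(mean_m1 = mean(x), mean_m2 = mean(y),
              difference = mean(x) - mean(y),
              t = tt$statistic, df = tt$df, p = tt$p.value)
  if (log2scale)
    out$p_log2 <- pairedT(log2(x + 1), log2(y + 1))$p.value
  out
}
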