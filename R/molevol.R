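# In-house evolutionary distances: Nei-Gojobori (1986) codon counting with
# equal-weight pathway averaging for Ka/Ks/omega, the Jukes-Cantor (1969)
# multiple-hit correction for non-coding (ACR) divergence, and GERP-based
# genetic load.
#
# Conventions (documented in the methods vignette): synonymous site
# fractions count mutations to stop codons as nonsynonymous, keeping
# s + n = 3 per codon; substitution pathways passing through a stop codon
# are excluded from the equal-weight average (all pathways are used if every
# one is blocked).  Codons containing a gap or non-ACGT character in either
# sequence are skipped entirely.

.ngCache <- new.env(parent = emptyenv())

.codonTable <- function() {
  if (!is.null(.ngCache$aa)) return(invisible(NULL))
  gc <- Biostrings::GENETIC_CODE
  .ngCache$aa <- gc
  codons <- names(gc)
  syn <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (gc[[cd]] == "*") { syn[cd] <- NA_real_; next }
    s <- 0
    for (p in 1:3) for (nt in c("A", "C", "G", "T")) {
      if (substr(cd, p, p) == nt) next
      alt <- cd
      substr(alt, p, p) <- nt
      # mutations to stop codons count as nonsynonymous
      if (gc[[alt]] != "*" && gc[[alt]] == gc[[cd]]) s <- s + 1 / 3
    }
    syn[cd] <- s
  }
  .ngCache$syn <- syn
  .ngCache$pair <- new.env(parent = emptyenv())
  invisible(NULL)
}

# equal-weight pathway-averaged (syn, nonsyn) differences between two
# non-stop codons; pathways through stop codons excluded when possible
.ngPairDiff <- function(c1, c2) {
  .codonTable()
  key <- paste0(c1, c2)
  hit <- .ngCache$pair[[key]]
  if (!is.null(hit)) return(hit)
  gc <- .ngCache$aa
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  res <- if (!length(pos)) c(0, 0) else {
    perms <- .permutations(pos)
    paths <- lapply(perms, function(ord) {
      cur <- c1; sd <- 0; nd <- 0; blocked <- FALSE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (gc[[nxt]] == "*") blocked <- TRUE
        if (gc[[nxt]] == gc[[cur]] && gc[[nxt]] != "*") sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      list(sd = sd, nd = nd, blocked = blocked)
    })
    keep <- !vapply(paths, `[[`, logical(1), "blocked")
    if (!any(keep)) keep <- rep(TRUE, length(paths))
    use <- paths[keep]
    c(mean(vapply(use, `[[`, numeric(1), "sd")),
      mean(vapply(use, `[[`, numeric(1), "nd")))
  }
  assign(key, res, envir = .ngCache$pair)
  res
}

.permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(.permutations(x[-i]), function(r) c(x[i], r)))
  out
}

.splitCodons <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  if (n %% 3 != 0) stop("sequence length not divisible by 3")
  substring(s, seq(1, n, 3), seq(3, n, 3))
}

#' Jukes-Cantor multiple-hit correction
#'
#' \eqn{d = -\frac{3}{4}\log(1 - \frac{4}{3}p)}.  Errors at saturation
#' (`p >= 0.75`).
#'
#' @param p proportion of differing sites.
#' @return corrected distance.
#' @export
jcCorrect <- function(p) {
  if (any(p >= 0.75))
    stop("saturation: proportion of differences >= 0.75, ",
         "Jukes-Cantor correction undefined")
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) Ka/Ks on a pairwise codon alignment
#'
#' Synonymous (S) and nonsynonymous (N) site counts are averaged over the
#' two sequences; observed differences in multi-difference codons are
#' averaged over all substitution pathways with equal weight (pathways via
#' stop codons excluded); the proportions pS = Sd/S and pN = Nd/N are each
#' corrected with the Jukes-Cantor formula.  Codons with a gap or non-ACGT
#' character in either sequence are skipped.
#'
#' @param seq1,seq2 aligned CDS strings of equal length divisible by 3, gap
#'   symbol `-`.  In-frame stop codons must have been masked to gaps.
#' @return a list with elements `ka`, `ks`, `omega` (NA when Ks = 0), `S`,
#'   `N`, `Sd`, `Nd` and `n_codons` (codons used).
#' @examples
#' ng86("TTTGGGATT", "TTTGGGATC")
#' @export
ng86 <- function(seq1, seq2) {
  .codonTable()
  if (nchar(seq1) != nchar(seq2)) stop("aligned sequences differ in length")
  cod1 <- .splitCodons(seq1)
  cod2 <- .splitCodons(seq2)
  okc <- grepl("^[ACGT]{3}$", cod1) & grepl("^[ACGT]{3}$", cod2)
  cod1 <- cod1[okc]; cod2 <- cod2[okc]
  stop1 <- !is.na(cod1) & is.na(.ngCache$syn[cod1])
  stop2 <- !is.na(cod2) & is.na(.ngCache$syn[cod2])
  if (any(stop1 | stop2))
    stop("in-frame stop codon in alignment; mask stops to '-' first")
  if (!length(cod1)) stop("zero countable codons in alignment")
  S <- sum((.ngCache$syn[cod1] + .ngCache$syn[cod2]) / 2)
  N <- 3 * length(cod1) - S
  diffs <- vapply(which(cod1 != cod2), function(i)
    .ngPairDiff(cod1[i], cod2[i]), numeric(2))
  Sd <- if (length(diffs)) sum(diffs[1, ]) else 0
  Nd <- if (length(diffs)) sum(diffs[2, ]) else 0
  pS <- Sd / S
  pN <- Nd / N
  ks <- jcCorrect(pS)
  ka <- jcCorrect(pN)
  list(ka = ka, ks = ks,
       omega = if (ks > 0) ka / ks else NA_real_,
       S = S, N = N, Sd = Sd, Nd = Nd, n_codons = length(cod1))
}

#' Ka/Ks for many pairs of sequences
#'
#' @param seqs a named character vector or [Biostrings::DNAStringSet] of
#'   aligned CDS sequences.
#' @param pairs a data.frame with columns `id1`, `id2` naming sequences in
#'   `seqs`.
#' @return a `data.table` with `id1`, `id2`, `ka`, `ks`, `omega`,
#'   `n_codons`; rows where the distance is undefined (saturation, missing
#'   sequence) carry NA.
#' @export
ng86Table <- function(seqs, pairs) {
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- unname(seqs[pairs$id1[i]])[1]
    b <- unname(seqs[pairs$id2[i]])[1]
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b))
      return(list(ka = NA_real_, ks = NA_real_, omega = NA_real_,
                  n_codons = NA_integer_))
    r <- tryCatch(ng86(a, b), error = function(e)
      list(ka = NA_real_, ks = NA_real_, omega = NA_real_,
           n_codons = NA_integer_))
    r[c("ka", "ks", "omega", "n_codons")]
  })
  cbind(data.table(id1 = pairs$id1, id2 = pairs$id2),
        rbindlist(lapply(res, as.data.table)))
}

#' Jukes-Cantor distance between two aligned nucleotide sequences
#'
#' Gap or ambiguous columns are excluded; `K = -3/4 log(1 - 4p/3)` on the
#' remaining mismatch proportion.  Used for the divergence of accessible
#' chromatin regions against their outgroup.
#'
#' @param seq1,seq2 aligned nucleotide strings of equal length.
#' @return numeric distance K (substitutions/site).
#' @examples
#' jcDistance("ACGTACGTAC", "ACGTACGTAT")
#' @export
jcDistance <- function(seq1, seq2) {
  if (nchar(seq1) != nchar(seq2)) stop("aligned sequences differ in length")
  a <- strsplit(toupper(seq1), "")[[1]]
  b <- strsplit(toupper(seq2), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("zero comparable sites")
  p <- sum(a[ok] != b[ok]) / sum(ok)
  jcCorrect(p)
}

#' GERP-based genetic load of a gene
#'
#' Putatively deleterious loci are nonsynonymous SNP sites with GERP score
#' strictly greater than zero.  The load is the panel-average count of
#' derived alleles at those sites divided by the gene-body length in bp.
#'
#' @param snps data.frame of SNPs within the gene with columns `class`
#'   (`"syn"`/`"nonsyn"`), `gerp`, and `snp_id` matching rows of `panel`.
#' @param geneLength gene-body length in bp (> 0).
#' @param panel numeric matrix of derived-allele counts, rows = SNPs (with
#'   rownames = `snp_id`), columns = panel individuals.
#' @return genetic load per bp (numeric scalar; 0 when no deleterious site).
#' @export
geneticLoad <- function(snps, geneLength, panel) {
  if (is.null(geneLength) || !is.finite(geneLength) || geneLength <= 0)
    stop("gene length must be > 0")
  if (is.null(panel) || ncol(panel) == 0)
    stop("empty genotype panel")
  snps <- as.data.table(snps)
  del <- snps[class == "nonsyn" & gerp > 0]
  if (!nrow(del)) return(0)
  idx <- intersect(del$snp_id, rownames(panel))
  if (!length(idx)) return(0)
  perInd <- colSums(panel[idx, , drop = FALSE])
  mean(perInd) / geneLength
}
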