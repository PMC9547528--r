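# Syntelog filtering, retention-status bookkeeping, chromatin-environment
# categories, duplicated block-pair construction and block statistics.

.CATEGORIES <- c("M1arm_M2arm", "M1peri_M2peri", "M1arm_M2peri",
                 "M1peri_M2arm")

#' Filter a raw syntelog table
#'
#' Removes tandem duplicates and rows whose divergence against the
#' outgroup fails the thresholds: `Ks < ksMin` (suspiciously recent, likely
#' not a WGD-derived syntelog) or `omega > omegaMax` (poor alignment or
#' pseudogenized).  Rows with missing Ks/omega are rejected with reason
#' `"incomplete"`.
#'
#' @param raw data.frame with columns `m1_gene`, `m2_gene` (NA when the
#'   copy is lost), `sorghum_gene`, `tandem` (logical), `ks`, `omega`
#'   (row-level divergence vs. the outgroup; for pairs, the pipeline
#'   supplies the more conservative of the two copies).
#' @param ksMin,omegaMax filter thresholds (defaults 0.05 and 2.0).
#' @return a list with `table` (the retained rows, plus a `status` column:
#'   `pair`, `singleton_m1`, `singleton_m2`) and `removed` (a removal log
#'   with a `reason` column: `tandem`, `Ks_min`, `omega_max`,
#'   `incomplete`).
#' @export
filterSyntelogs <- function(raw, ksMin = 0.05, omegaMax = 2.0) {
  tb <- as.data.table(raw)
  need <- c("m1_gene", "m2_gene", "sorghum_gene", "tandem", "ks", "omega")
  if (!all(need %in% names(tb)))
    stop("raw table must have columns ", paste(need, collapse = ", "))
  reason <- rep(NA_character_, nrow(tb))
  reason[is.na(tb$ks) | is.na(tb$omega)] <- "incomplete"
  reason[is.na(reason) & tb$omega > omegaMax] <- "omega_max"
  reason[is.na(reason) & tb$ks < ksMin] <- "Ks_min"
  reason[!is.na(tb$tandem) & tb$tandem] <- "tandem"
  keep <- is.na(reason)
  out <- tb[keep]
  out[, status := fifelse(!is.na(m1_gene) & !is.na(m2_gene), "pair",
                  fifelse(!is.na(m1_gene), "singleton_m1", "singleton_m2"))]
  if (any(is.na(out$m1_gene) & is.na(out$m2_gene)))
    stop("rows with both maize copies missing are not syntelogs")
  list(table = out,
       removed = data.table(tb[!keep], reason = reason[!keep]))
}

#' Annotate a homoeolog table with region classes and categories
#'
#' Each retained copy is classified as `arm` or `peri` by
#' [classifyRegion()]; pair rows additionally get one of the four
#' chromatin-environment categories `M1arm_M2arm`, `M1peri_M2peri`,
#' `M1arm_M2peri`, `M1peri_M2arm`.
#'
#' @param table a filtered homoeolog table (see [filterSyntelogs()]).
#' @param genes a named `GRanges` of gene models (names = gene ids).
#' @param partition a [GenomePartition-class].
#' @return the table with columns `m1_region`, `m2_region`, `category`
#'   added.
#' @export
assignCategory <- function(table, genes, partition) {
  tb <- copy(as.data.table(table))
  if (is.null(names(genes))) stop("'genes' must be a named GRanges")
  reg <- classifyRegion(genes, partition)
  names(reg) <- names(genes)
  tb[, m1_region := ifelse(is.na(m1_gene), NA_character_,
                           unname(reg[m1_gene]))]
  tb[, m2_region := ifelse(is.na(m2_gene), NA_character_,
                           unname(reg[m2_gene]))]
  miss <- tb[status == "pair" & (is.na(m1_region) | is.na(m2_region))]
  if (nrow(miss))
    stop(nrow(miss), " pair gene(s) missing from the gene annotation")
  tb[, category := NA_character_]
  tb[status == "pair", category := paste0(
    "M1", m1_region, "_M2", m2_region)]
  stopifnot(all(tb$category[tb$status == "pair"] %in% .CATEGORIES))
  tb[]
}

#' Singleton : WGD-gene ratio for a subgenome
#'
#' For the given subgenome (and optionally one region), counts retained
#' singleton genes (partner lost) and WGD genes (member of a retained
#' pair), and reports their ratio rounded to one decimal in the `x.y:1`
#' convention; raw counts are preserved.
#'
#' @param table an annotated homoeolog table (see [assignCategory()]; the
#'   region columns are only needed when `region` is given).
#' @param subgenome `"m1"` or `"m2"`.
#' @param region optional `"arm"` or `"peri"` restriction (location of the
#'   subgenome's own copy).
#' @return list with `n_singleton`, `n_wgd`, `ratio` (1-decimal; NA when
#'   `n_wgd` is 0) and `ratio_raw`.
#' @export
singletonWgdRatio <- function(table, subgenome = c("m1", "m2"),
                              region = NULL) {
  subgenome <- match.arg(subgenome)
  tb <- as.data.table(table)
  regcol <- paste0(subgenome, "_region")
  sel <- rep(TRUE, nrow(tb))
  if (!is.null(region)) {
    if (!regcol %in% names(tb))
      stop("table lacks region annotation; run assignCategory() first")
    sel <- !is.na(tb[[regcol]]) & tb[[regcol]] == region
  }
  nS <- sum(sel & tb$status == paste0("singleton_", subgenome))
  nW <- sum(sel & tb$status == "pair")
  raw <- if (nW > 0) nS / nW else NA_real_
  list(n_singleton = nS, n_wgd = nW,
       ratio = if (is.na(raw)) NA_real_ else round(raw, 1),
       ratio_raw = raw)
}

#' Build duplicated block pairs from a homoeolog table
#'
#' Blocks are maximal runs of syntelogs, in ancestral (outgroup) gene
#' order, that share the same maize1/maize2 chromosome pairing.  Singleton
#' rows join the current block when the chromosome of their retained copy
#' matches.  Blocks with fewer than `minGenes` genes on either side are
#' dropped.  The environment class of each side is the majority region of
#' its member genes.
#'
#' @param table annotated homoeolog table with region columns.
#' @param genes named `GRanges` of gene models.
#' @param minGenes minimum genes per side (default 5).
#' @param ancestralOrder optional character vector giving the ancestral
#'   order of `sorghum_gene` ids; defaults to their sort order.
#' @return a list with `blocks` (one row per block pair: ids, chromosome
#'   pairing, per-side intervals, gene/singleton/pair counts, majority
#'   regions, retention rates) and `members` (the input rows plus a
#'   `block` id column; NA for rows in dropped blocks).
#' @export
buildBlocks <- function(table, genes, minGenes = 5L, ancestralOrder = NULL) {
  tb <- copy(as.data.table(table))
  ord <- if (is.null(ancestralOrder)) order(tb$sorghum_gene) else
    order(match(tb$sorghum_gene, ancestralOrder))
  tb <- tb[ord]
  pos <- function(ids) {
    p <- rep(NA_real_, length(ids))
    hit <- !is.na(ids) & ids %in% names(genes)
    g <- genes[ids[hit]]
    p[hit] <- (start(g) + end(g)) / 2
    p
  }
  chromOf <- function(ids) {
    p <- rep(NA_character_, length(ids))
    hit <- !is.na(ids) & ids %in% names(genes)
    p[hit] <- as.character(seqnames(genes[ids[hit]]))
    p
  }
  tb[, m1_chrom := chromOf(m1_gene)]
  tb[, m2_chrom := chromOf(m2_gene)]
  blockid <- integer(nrow(tb))
  cur <- 0L; c1 <- NA_character_; c2 <- NA_character_
  for (i in seq_len(nrow(tb))) {
    k1 <- tb$m1_chrom[i]; k2 <- tb$m2_chrom[i]
    compatible <- cur > 0L &&
      (is.na(k1) || is.na(c1) || k1 == c1) &&
      (is.na(k2) || is.na(c2) || k2 == c2)
    if (!compatible) {
      cur <- cur + 1L
      c1 <- NA_character_; c2 <- NA_character_
    }
    if (!is.na(k1)) c1 <- k1
    if (!is.na(k2)) c2 <- k2
    blockid[i] <- cur
  }
  tb[, block := blockid]
  summ <- tb[, {
    nPair <- sum(status == "pair")
    nS1 <- sum(status == "singleton_m1")
    nS2 <- sum(status == "singleton_m2")
    p1 <- pos(m1_gene); p2 <- pos(m2_gene)
    maj <- function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) NA_character_
      else names(sort(table(x), decreasing = TRUE))[1]
    }
    list(m1_chrom = m1_chrom[!is.na(m1_chrom)][1],
         m2_chrom = m2_chrom[!is.na(m2_chrom)][1],
         m1_start = suppressWarnings(min(p1, na.rm = TRUE)),
         m1_end = suppressWarnings(max(p1, na.rm = TRUE)),
         m2_start = suppressWarnings(min(p2, na.rm = TRUE)),
         m2_end = suppressWarnings(max(p2, na.rm = TRUE)),
         n_pairs = nPair, n_singleton_m1 = nS1, n_singleton_m2 = nS2,
         n_genes_m1 = nPair + nS1, n_genes_m2 = nPair + nS2,
         m1_region = maj(m1_region), m2_region = maj(m2_region))
  }, by = block]
  keep <- summ[summ$n_genes_m1 >= minGenes & summ$n_genes_m2 >= minGenes]
  keep[, `:=`(
    retention_m1 = (n_singleton_m1 + n_pairs) /
      (n_singleton_m1 + n_singleton_m2 + n_pairs),
    retention_m2 = (n_singleton_m2 + n_pairs) /
      (n_singleton_m1 + n_singleton_m2 + n_pairs))]
  keep[, category := paste0("M1", m1_region, "_M2", m2_region)]
  tb[!block %in% keep$block, block := NA_integer_]
  list(blocks = keep[], members = tb[])
}

#' Block retention rate
#'
#' Per-block retention of one subgenome out of the ancestral genes of the
#' block: `(side singletons + WGD genes) / (m1 singletons + m2 singletons
#' + WGD genes)`.
#'
#' @param nSingleton1,nSingleton2 singleton counts of the two subgenomes in
#'   the block.
#' @param nWgd retained pair count of the block.
#' @param side `"m1"` or `"m2"`: whose retention to compute.
#' @return retention fraction in (0, 1\]; NA when the denominator is 0.
#' @examples
#' retentionRate(2, 1, 3, "m1")  # 5/6
#' @export
retentionRate <- function(nSingleton1, nSingleton2, nWgd,
                          side = c("m1", "m2")) {
  side <- match.arg(side)
  stopifnot(nSingleton1 >= 0, nSingleton2 >= 0, nWgd >= 0)
  den <- nSingleton1 + nSingleton2 + nWgd
  if (den == 0) return(NA_real_)
  num <- nWgd + if (side == "m1") nSingleton1 else nSingleton2
  num / den
}

#' Fill block statistics: size, density, TE content, recombination
#'
#' For each block side: block size is the spanned Mb, gene density the
#' member genes per Mb, TE content the summed overlap (Mb) with the block
#' interval per TE class, and the recombination rate the mean map rate at
#' the positions of the block's duplicated (pair) genes.
#'
#' @param blocks the `blocks` table from [buildBlocks()].
#' @param members the `members` table from [buildBlocks()].
#' @param genes named `GRanges` of gene models.
#' @param tes `GRanges` of TE annotations with a metadata column `class`
#'   (e.g. `"LTR"`, `"DNA"`).
#' @param recmap a `recombMap` (see [recombinationRate()]), or NULL to skip.
#' @return `blocks` with per-side columns added: `size_mb_*`,
#'   `gene_density_*`, `te_mb_*`, `te_LTR_mb_*`, `te_DNA_mb_*`,
#'   `recomb_*` (NA where a block lies outside the marker map).
#' @export
blockStats <- function(blocks, members, genes, tes, recmap = NULL) {
  bl <- copy(as.data.table(blocks))
  mem <- as.data.table(members)
  teClass <- if (!is.null(mcols(tes)$class)) as.character(mcols(tes)$class)
             else rep("TE", length(tes))
  teOverlapMb <- function(ch, s, e, cls = NULL) {
    if (is.na(ch) || !is.finite(s) || !is.finite(e)) return(NA_real_)
    sel <- as.character(seqnames(tes)) == ch &
      (if (is.null(cls)) TRUE else teClass == cls)
    tt <- IRanges::reduce(ranges(tes[sel]))
    win <- IRanges(as.integer(s), as.integer(e))
    sum(width(IRanges::intersect(tt, win))) / 1e6
  }
  for (sideTag in c("m1", "m2")) {
    chcol <- paste0(sideTag, "_chrom")
    scol <- paste0(sideTag, "_start"); ecol <- paste0(sideTag, "_end")
    sz <- (bl[[ecol]] - bl[[scol]]) / 1e6
    bl[, paste0("size_mb_", sideTag) := sz]
    bl[, paste0("gene_density_", sideTag) :=
         bl[[paste0("n_genes_", sideTag)]] / pmax(sz, 1e-9)]
    bl[, paste0("te_mb_", sideTag) := mapply(
      teOverlapMb, bl[[chcol]], bl[[scol]], bl[[ecol]])]
    for (cls in unique(teClass))
      bl[, paste0("te_", cls, "_mb_", sideTag) := mapply(
        teOverlapMb, bl[[chcol]], bl[[scol]], bl[[ecol]],
        MoreArgs = list(cls = cls))]
    if (!is.null(recmap)) {
      gcol <- paste0(sideTag, "_gene")
      rec <- vapply(bl$block, function(b) {
        ids <- mem[block == b & status == "pair"][[gcol]]
        ids <- ids[!is.na(ids) & ids %in% names(genes)]
        if (!length(ids)) return(NA_real_)
        g <- genes[ids]
        mean(recombRateAt(recmap, as.character(seqnames(g)),
                          (start(g) + end(g)) / 2), na.rm = TRUE)
      }, numeric(1))
      bl[, paste0("recomb_", sideTag) := rec]
    }
  }
  bl[]
}
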