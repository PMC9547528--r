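# Accessible chromatin regions: genic/proximal/distal distance classes,
# subgenome retention ratios, five-way syntenic-ACR retention categories,
# accessibility comparison, and chromatin-loop region counts.

#' Classify ACRs by distance to the nearest gene
#'
#' genic = overlaps a gene; proximal = within 2 kb of a gene (inclusive);
#' distal = more than 2 kb from any gene.  Nearest genes are found by
#' edge-to-edge distance.
#'
#' @param acrs `GRanges` of ACR intervals (a `score` metadata column is
#'   carried through if present).
#' @param genes named `GRanges` of gene models.
#' @param proximalMax distance boundary in bp (default 2000; exactly
#'   2000 bp is proximal).
#' @return `acrs` with metadata columns `nearest_gene`, `distance`,
#'   `dist_class` added.  ACRs on chromosomes without genes are classed
#'   distal with NA nearest gene, with a warning.
#' @export
classifyAcr <- function(acrs, genes, proximalMax = 2000) {
  h <- .sameSeqlevels(acrs, genes)
  hits <- distanceToNearest(h[[1]], h[[2]], ignore.strand = TRUE)
  ng <- rep(NA_character_, length(acrs))
  dist <- rep(NA_real_, length(acrs))
  qh <- S4Vectors::queryHits(hits)
  ng[qh] <- names(genes)[S4Vectors::subjectHits(hits)]
  dist[qh] <- mcols(hits)$distance
  cls <- rep(NA_character_, length(acrs))
  cls[!is.na(dist) & dist == 0] <- "genic"
  cls[!is.na(dist) & dist > 0 & dist <= proximalMax] <- "proximal"
  cls[!is.na(dist) & dist > proximalMax] <- "distal"
  if (anyNA(cls)) {
    warning(sum(is.na(cls)),
            " ACR(s) on chromosomes without genes: classed distal, ",
            "nearest gene NA")
    cls[is.na(cls)] <- "distal"
  }
  mcols(acrs)$nearest_gene <- ng
  mcols(acrs)$distance <- dist
  mcols(acrs)$dist_class <- cls
  acrs
}

#' ACR singleton : WGD retention ratio for a subgenome
#'
#' Counts ACRs whose nearest gene is a retained singleton of the
#' subgenome versus ACRs whose nearest gene is a WGD (pair) gene of the
#' subgenome.  ACRs whose nearest gene has no outgroup syntelog (absent
#' from the homoeolog table) are excluded.
#'
#' @param acrs classified ACRs (see [classifyAcr()]).
#' @param table annotated homoeolog table (see [assignCategory()]).
#' @param subgenome `"m1"` or `"m2"`.
#' @return list with `n_near_singleton`, `n_near_wgd`, `ratio`
#'   (1-decimal; NA if no WGD-adjacent ACR), `ratio_raw`, `n_excluded`.
#' @export
acrRetentionRatio <- function(acrs, table, subgenome = c("m1", "m2")) {
  subgenome <- match.arg(subgenome)
  tb <- as.data.table(table)
  gcol <- paste0(subgenome, "_gene")
  statusOf <- tb$status
  names(statusOf) <- tb[[gcol]]
  ng <- mcols(acrs)$nearest_gene
  st <- statusOf[ng]
  excluded <- sum(is.na(st))
  nS <- sum(st == paste0("singleton_", subgenome), na.rm = TRUE)
  nW <- sum(st == "pair", na.rm = TRUE)
  raw <- if (nW > 0) nS / nW else NA_real_
  list(n_near_singleton = nS, n_near_wgd = nW,
       ratio = if (is.na(raw)) NA_real_ else round(raw, 1),
       ratio_raw = raw, n_excluded = excluded)
}

#' Assign the five syntenic-ACR retention categories
#'
#' For maize ACRs with an outgroup-syntenic record in the homology table:
#' near WGD genes, category 1 = both homoeologous ACRs retained, 2 =
#' retained in maize1 only, 3 = retained in maize2 only; near singleton
#' genes, 4 = retained in maize1, 5 = retained in maize2.
#'
#' @param homology data.frame with one row per retained maize ACR:
#'   `acr_id`, `subgenome` (`"m1"`/`"m2"`), `partner_acr` (id of the
#'   homoeologous ACR in the other subgenome, NA when lost), `sorghum_acr`
#'   (NA when the ACR has no outgroup syntenic ACR) and `near_status`
#'   (`"wgd"` or `"singleton"`).
#' @return the table with a `category` column (integer 1-5; NA for ACRs
#'   without an outgroup syntenic ACR, with a warning).
#' @export
assignRetentionCategory <- function(homology) {
  tb <- copy(as.data.table(homology))
  need <- c("acr_id", "subgenome", "partner_acr", "sorghum_acr",
            "near_status")
  if (!all(need %in% names(tb)))
    stop("homology table must have columns ", paste(need, collapse = ", "))
  tb[, category := NA_integer_]
  syn <- !is.na(tb$sorghum_acr)
  if (any(!syn))
    warning(sum(!syn), " ACR(s) without syntenic outgroup ACR: category NA")
  paired <- !is.na(tb$partner_acr)
  tb[syn & near_status == "wgd" & paired, category := 1L]
  tb[syn & near_status == "wgd" & !paired & subgenome == "m1",
     category := 2L]
  tb[syn & near_status == "wgd" & !paired & subgenome == "m2",
     category := 3L]
  tb[syn & near_status == "singleton" & subgenome == "m1", category := 4L]
  tb[syn & near_status == "singleton" & subgenome == "m2", category := 5L]
  tb[]
}

#' Compare chromatin accessibility between two groups of ACRs
#'
#' Unpaired Student's t-test on accessibility scores.
#'
#' @param scores numeric accessibility scores.
#' @param group a two-level factor/character vector parallel to `scores`.
#' @return a `data.table` with one row per group (n, mean, median) plus
#'   attributes-free columns `t`, `p` repeated on each row; NA when a
#'   group has fewer than two members.
#' @export
accessibilityCompare <- function(scores, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("need exactly two groups")
  dt <- data.table(score = scores, group = g)
  summ <- dt[, .(n = .N, mean = mean(score), median = stats::median(score)),
             by = group]
  if (any(summ$n < 2)) {
    summ[, `:=`(t = NA_real_, p = NA_real_)]
    return(summ[])
  }
  tt <- stats::t.test(score ~ group, data = dt, var.equal = FALSE)
  summ[, `:=`(t = unname(tt$statistic), p = tt$p.value)]
  summ[]
}

#' Count chromatin loops by subgenome and region
#'
#' Each loop is assigned by the partition classes of its two anchor
#' midpoints: loops with both anchors in the same subgenome x region
#' combination are counted there; loops whose anchors disagree are
#' counted under `"mixed"` (and excluded from per-region comparisons by
#' default downstream).
#'
#' @param loops data.frame in BEDPE column order: `chrom1`, `start1`,
#'   `end1`, `chrom2`, `start2`, `end2` (0-based half-open).
#' @param partition a [GenomePartition-class].
#' @param subgenomeMap named character vector chromosome -> subgenome
#'   (`"m1"`/`"m2"`).
#' @return a `data.table` of counts with columns `label`
#'   (`m1_arm`, `m1_peri`, `m2_arm`, `m2_peri`, `mixed`) and `n`; loops
#'   with anchors off the partition are skipped with a warning.
#' @export
loopRegionCounts <- function(loops, partition, subgenomeMap) {
  lp <- as.data.table(loops)
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (!all(need %in% names(lp)))
    stop("loops must have BEDPE columns ", paste(need, collapse = ", "))
  labels <- c("m1_arm", "m1_peri", "m2_arm", "m2_peri", "mixed")
  counts <- setNames(integer(length(labels)), labels)
  anchorLabel <- function(ch, s, e) {
    # BEDPE 0-based half-open -> 1-based midpoint
    if (!ch %in% names(subgenomeMap)) return(NA_character_)
    mid <- floor((s + e) / 2) + 1L
    gr <- GRanges(ch, IRanges(mid, width = 1L))
    reg <- tryCatch(classifyRegion(gr, partition),
                    error = function(e) NA_character_)
    if (is.na(reg)) return(NA_character_)
    paste0(subgenomeMap[[ch]], "_", reg)
  }
  skipped <- 0L
  for (i in seq_len(nrow(lp))) {
    a <- anchorLabel(lp$chrom1[i], lp$start1[i], lp$end1[i])
    b <- anchorLabel(lp$chrom2[i], lp$start2[i], lp$end2[i])
    if (is.na(a) || is.na(b)) { skipped <- skipped + 1L; next }
    lab <- if (a == b) a else "mixed"
    counts[lab] <- counts[lab] + 1L
  }
  if (skipped)
    warning(skipped, " loop(s) with anchors off the partition skipped")
  data.table(label = labels, n = as.integer(counts))
}
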