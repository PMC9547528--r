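# End-to-end orchestration: partition -> syntelog filtering and
# categories -> blocks -> evolutionary distances -> dominance -> ACRs ->
# loops -> report.

#' Run the full subgenome-dominance analysis on a dataset directory
#'
#' Executes every stage on the files of `dir` (the layout written by
#' [generateDataset()]): windowed density/recombination tracks and
#' arm/peri segmentation; Ka/Ks/omega of every retained gene against its
#' outgroup syntelog (conservative row-level values: min Ks, max omega of
#' the two copies); syntelog filtering, category assignment and
#' singleton:WGD ratios; block construction and block statistics; Ka/Ks
#' between homoeologs; horse-race dominance and paired expression tests;
#' ACR distance classes, retention ratios and categories; chromatin-loop
#' counts; and the tabular report.
#'
#' @param dir dataset directory.
#' @param outDir optional directory for report TSV/JSON output.
#' @param profiles also compute the siRNA/methylation/TE metaprofiles for
#'   the M1arm_M2arm pairs (slower; default TRUE).
#' @param minExpr,fold horse-race parameters (defaults 1 FPKM, 2-fold).
#' @return a named list of stage outputs (see Details in the vignette).
#' @export
runPipeline <- function(dir, outDir = NULL, profiles = TRUE,
                        minExpr = 1.0, fold = 2.0) {
  ds <- readDataset(dir, tracks = profiles)
  res <- list()
  # --- partition
  recmap <- recombinationRate(ds$markers)
  track <- windowStats(ds$genes, ds$tes, ds$chromLengths)
  cen <- GRanges(ds$truth$centromere$chrom,
                 IRanges(ds$truth$centromere$start,
                         ds$truth$centromere$end),
                 seqlengths = ds$chromLengths)
  part <- segmentGenome(track, cen, ds$chromLengths, recmap = recmap)
  res$partition <- part
  # --- per-copy divergence vs the outgroup, then the syntelog filter
  syn <- as.data.table(ds$syntelogs)
  allSeqs <- c(as.character(ds$maizeCds), as.character(ds$sorghumCds))
  divOf <- function(gcol) {
    ok <- !is.na(syn[[gcol]])
    pr <- data.table(id1 = syn[[gcol]][ok], id2 = syn$sorghum_gene[ok])
    kk <- ng86Table(allSeqs, pr)
    out <- data.table(ks = rep(NA_real_, nrow(syn)),
                      omega = rep(NA_real_, nrow(syn)))
    out$ks[ok] <- kk$ks
    out$omega[ok] <- kk$omega
    out
  }
  d1 <- divOf("m1_gene"); d2 <- divOf("m2_gene")
  syn[, ks := pmin(d1$ks, d2$ks, na.rm = TRUE)]
  syn[, omega := pmax(d1$omega, d2$omega, na.rm = TRUE)]
  syn[is.na(d1$ks) & is.na(d2$ks), ks := NA_real_]
  syn[is.na(d1$omega) & is.na(d2$omega), omega := NA_real_]
  res$divergence_vs_outgroup <- data.table(
    syn[, .(m1_gene, m2_gene, sorghum_gene)],
    ks_m1 = d1$ks, omega_m1 = d1$omega,
    ks_m2 = d2$ks, omega_m2 = d2$omega)
  filt <- filterSyntelogs(syn)
  res$removed <- filt$removed
  tab <- assignCategory(filt$table, ds$genes, part)
  res$homoeologs <- tab
  # --- singleton:WGD ratios
  res$ratios <- rbindlist(lapply(
    expand.grid(sub = c("m1", "m2"), reg = c("arm", "peri"),
                stringsAsFactors = FALSE) |> split(seq_len(4)),
    function(g) {
      r <- singletonWgdRatio(tab, g$sub, g$reg)
      data.table(subgenome = g$sub, region = g$reg,
                 n_singleton = r$n_singleton, n_wgd = r$n_wgd,
                 ratio = r$ratio)
    }))
  # --- blocks
  bl <- buildBlocks(tab, ds$genes)
  bl$blocks <- blockStats(bl$blocks, bl$members, ds$genes, ds$tes, recmap)
  res$blocks <- bl$blocks
  res$block_members <- bl$members
  # --- homoeolog Ka/Ks by category
  pairs <- tab[status == "pair"]
  kk <- ng86Table(allSeqs,
                  data.table(id1 = pairs$m1_gene, id2 = pairs$m2_gene))
  res$pair_kaks <- data.table(pairs[, .(m1_gene, m2_gene, category)],
                              ka = kk$ka, ks = kk$ks, omega = kk$omega)
  # per-copy Ka against the outgroup, paired within pairs by category
  pk <- data.table(pairs[, .(m1_gene, m2_gene, category)],
                   ka_m1 = ng86Table(allSeqs,
                     data.table(id1 = pairs$m1_gene,
                                id2 = pairs$sorghum_gene))$ka,
                   ka_m2 = ng86Table(allSeqs,
                     data.table(id1 = pairs$m2_gene,
                                id2 = pairs$sorghum_gene))$ka)
  res$pair_branch_ka <- pk
  # --- dominance
  dom <- dominanceSummary(ds$fpkm, pairs, fold = fold, minExpr = minExpr)
  res$dominance <- dom
  res$expression_tests <- rbindlist(lapply(split(pairs, pairs$category),
    function(pp) {
      if (nrow(pp) < 2) return(NULL)
      mc <- meanExpressionCompare(ds$fpkm, pp)
      data.table(category = pp$category[1], mean_m1 = mc$mean_m1,
                 mean_m2 = mc$mean_m2, p = mc$p, p_log2 = mc$p_log2)
    }))
  # --- ACRs
  acrs <- classifyAcr(ds$acrs, ds$genes)
  res$acrs <- acrs
  res$acr_ratios <- rbindlist(lapply(c("m1", "m2"), function(s) {
    r <- acrRetentionRatio(acrs, tab, s)
    data.table(subgenome = s, n_near_singleton = r$n_near_singleton,
               n_near_wgd = r$n_near_wgd, ratio = r$ratio)
  }))
  res$acr_categories <- assignRetentionCategory(ds$homology)
  acrSub <- substr(mcols(acrs)$acr_id, 5, 6)
  acrReg <- classifyRegion(acrs, part)
  res$acr_accessibility <- rbindlist(lapply(c("arm", "peri"), function(rg) {
    sel <- acrReg == rg
    if (length(unique(acrSub[sel])) < 2) return(NULL)
    cmp <- accessibilityCompare(mcols(acrs)$score[sel], acrSub[sel])
    data.table(region = rg, cmp)
  }))
  subMap <- setNames(substr(names(ds$chromLengths), 1, 2),
                     names(ds$chromLengths))
  res$loops <- loopRegionCounts(ds$loops, part, subMap)
  # --- profiles for the arm-arm pairs
  if (profiles) {
    aa <- pairs[category == "M1arm_M2arm"]
    g1 <- ds$genes[aa$m1_gene]; g2 <- ds$genes[aa$m2_gene]
    res$profiles <- list(
      sirna_m1 = sirnaProfile(ds$sirna, g1,
                              chromLengths = ds$chromLengths),
      sirna_m2 = sirnaProfile(ds$sirna, g2,
                              chromLengths = ds$chromLengths),
      chh_m1 = methylationProfile(ds$methylation, g1, "CHH",
                                  chromLengths = ds$chromLengths),
      chh_m2 = methylationProfile(ds$methylation, g2, "CHH",
                                  chromLengths = ds$chromLengths),
      te_m1 = teProportionProfile(g1, ds$tes,
                                  chromLengths = ds$chromLengths),
      te_m2 = teProportionProfile(g2, ds$tes,
                                  chromLengths = ds$chromLengths))
    res$te_distance <- data.table(
      category = pairs$category,
      d_m1 = nearestTeDistance(ds$genes[pairs$m1_gene], ds$tes),
      d_m2 = nearestTeDistance(ds$genes[pairs$m2_gene], ds$tes))
  }
  # --- genetic load per pair gene
  snps <- ds$snps
  span <- unique(width(ds$genes))[1]
  loadOf <- function(ids) {
    vapply(ids, function(g) {
      s <- snps[snps$gene == g, ]
      if (!nrow(s)) return(0)
      geneticLoad(s, span, ds$panel)
    }, numeric(1))
  }
  res$genetic_load <- data.table(
    category = pairs$category,
    load_m1 = loadOf(pairs$m1_gene),
    load_m2 = loadOf(pairs$m2_gene))
  # --- report
  res$report <- buildReport(res)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    fwrite(res$report, file.path(outDir, "report.tsv"), sep = "\t")
    jsonlite::write_json(res$report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  res
}

#' Assemble the block/category comparison report
#'
#' One row per statistic per chromatin-environment comparison, mirroring
#' the block-table layout of subgenome-dominance studies: block counts,
#' singleton vs. WGD counts with a chi-square P, per-side means +/- SD
#' with a paired-t P for gene counts, block sizes, gene densities,
#' retention rates, TE content and recombination rates, plus the
#' category-level Ka and dominance summaries.
#'
#' @param res a stage-output list from [runPipeline()] (needs at least
#'   `homoeologs`, `blocks`; other sections are included when present,
#'   missing stages are reported as explicit gaps).
#' @return a long-format `data.table` with columns `comparison`,
#'   `statistic`, `m1_value`, `m2_value`, `m1_sd`, `m2_sd`, `test`, `p`.
#' @export
buildReport <- function(res) {
  rows <- list()
  addRow <- function(comparison, statistic, m1v, m2v, m1s = NA_real_,
                     m2s = NA_real_, test = NA_character_, p = NA_real_)
    rows[[length(rows) + 1L]] <<- data.table(
      comparison = comparison, statistic = statistic,
      m1_value = m1v, m2_value = m2v, m1_sd = m1s, m2_sd = m2s,
      test = test, p = p)
  if (is.null(res$blocks) || is.null(res$homoeologs)) {
    addRow("all", "missing_stage", NA_real_, NA_real_,
           test = "none", p = NA_real_)
    return(rbindlist(rows))
  }
  tab <- as.data.table(res$homoeologs)
  bl <- as.data.table(res$blocks)
  for (cat in .CATEGORIES) {
    bb <- bl[bl$category == cat, ]
    addRow(cat, "n_blocks", nrow(bb), nrow(bb))
    # singletons vs WGD genes within the category's blocks
    mem <- as.data.table(res$block_members)
    mm <- mem[!is.na(block) & block %in% bb$block]
    s1 <- sum(mm$status == "singleton_m1")
    s2 <- sum(mm$status == "singleton_m2")
    wg <- sum(mm$status == "pair")
    pchi <- if (min(s1 + wg, s2 + wg) > 0 && (s1 + s2) > 0 && wg > 0)
      tryCatch(chiSquare(matrix(c(s1, s2, wg, wg), 2))$p.value,
               error = function(e) NA_real_) else NA_real_
    addRow(cat, "singletons_vs_wgd", s1, s2, test = "chi_square", p = pchi)
    addRow(cat, "n_wgd_genes", wg, wg)
    pairedStat <- function(stat, v1, v2) {
      ok <- is.finite(v1) & is.finite(v2)
      p <- if (sum(ok) >= 2) pairedT(v1[ok], v2[ok])$p.value else NA_real_
      addRow(cat, stat, mean(v1[ok]), mean(v2[ok]),
             stats::sd(v1[ok]), stats::sd(v2[ok]), "paired_t", p)
    }
    if (nrow(bb)) {
      pairedStat("n_genes", bb$n_genes_m1, bb$n_genes_m2)
      pairedStat("block_size_mb", bb$size_mb_m1, bb$size_mb_m2)
      pairedStat("gene_density", bb$gene_density_m1, bb$gene_density_m2)
      pairedStat("retention_rate", bb$retention_m1, bb$retention_m2)
      pairedStat("te_mb", bb$te_mb_m1, bb$te_mb_m2)
      if ("te_LTR_mb_m1" %in% names(bb))
        pairedStat("te_LTR_mb", bb$te_LTR_mb_m1, bb$te_LTR_mb_m2)
      if ("te_DNA_mb_m1" %in% names(bb))
        pairedStat("te_DNA_mb", bb$te_DNA_mb_m1, bb$te_DNA_mb_m2)
      if ("recomb_m1" %in% names(bb))
        pairedStat("recombination", bb$recomb_m1, bb$recomb_m2)
    }
    if (!is.null(res$pair_branch_ka)) {
      pk <- as.data.table(res$pair_branch_ka)[category == cat]
      if (nrow(pk) >= 2) pairedStat("ka_vs_outgroup", pk$ka_m1, pk$ka_m2)
    }
    if (!is.null(res$genetic_load)) {
      gl <- as.data.table(res$genetic_load)[category == cat]
      if (nrow(gl) >= 2) pairedStat("genetic_load", gl$load_m1, gl$load_m2)
    }
    if (!is.null(res$dominance)) {
      ds <- as.data.table(res$dominance$summary)[category == cat]
      if (nrow(ds))
        addRow(cat, "pct_dominant", ds$pct_maize1, ds$pct_maize2)
    }
  }
  rbindlist(rows)
}
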