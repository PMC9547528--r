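rawRow <- function(m1 = "a1", m2 = "b1", sb = "s1", tandem = FALSE,
                   ks = 0.7, omega = 0.3)
  data.frame(m1_gene = m1, m2_gene = m2, sorghum_gene = sb,
             tandem = tandem, ks = ks, omega = omega)

test_that("syntelog filter removes tandem, low-Ks and high-omega rows", {
  raw <- rbind(
    rawRow("a1", "b1", "s1"),
    rawRow("a2", "b2", "s2", ks = 0.04),          # Ks below 0.05
    rawRow("a3", "b3", "s3", omega = 2.5),        # omega above 2.0
    rawRow("a4", NA, "s4"),
    rawRow("a5", "b5", "s5"))
  f <- filterSyntelogs(raw)
  expect_equal(nrow(f$table), 3L)
  expect_equal(nrow(f$removed), 2L)
  expect_setequal(f$removed$reason, c("Ks_min", "omega_max"))
  expect_equal(f$table$status, c("pair", "singleton_m1", "pair"))
  # boundary semantics: Ks exactly at the threshold is kept
  expect_equal(nrow(filterSyntelogs(rawRow(ks = 0.05))$table), 1L)
  # tandem flag wins
  ft <- filterSyntelogs(rawRow(tandem = TRUE))
  expect_equal(ft$removed$reason, "tandem")
  # missing Ks -> incomplete
  fi <- filterSyntelogs(rawRow(ks = NA))
  expect_equal(fi$removed$reason, "incomplete")
})

test_that("category assignment covers pairs exactly and uses gene locations", {
  part <- toyPartition(chroms = c("chrA", "chrB"))
  genes <- GenomicRanges::GRanges(
    c("chrA", "chrA", "chrB", "chrB"),
    IRanges::IRanges(c(1e5, 5e6, 1e5, 5e6), width = 1e3))
  names(genes) <- c("a_arm", "a_peri", "b_arm", "b_peri")
  tb <- data.frame(
    m1_gene = c("a_arm", "a_arm", "a_peri", "a_peri"),
    m2_gene = c("b_arm", "b_peri", "b_arm", "b_peri"),
    sorghum_gene = paste0("s", 1:4), tandem = FALSE, ks = 0.7, omega = 0.3,
    status = "pair")
  got <- assignCategory(tb, genes, part)
  expect_equal(got$category, c("M1arm_M2arm", "M1arm_M2peri",
                               "M1peri_M2arm", "M1peri_M2peri"))
  expect_equal(sum(table(got$category)), nrow(got))
})

test_that("singleton:WGD ratios reproduce the published worked examples", {
  mkTable <- function(nS, nW, sub) {
    data.table::data.table(
      status = c(rep(paste0("singleton_", sub), nS), rep("pair", nW)))
  }
  # dominant subgenome, chromosomal arms: 5,937 singletons vs 3,597 WGD
  r <- singletonWgdRatio(mkTable(5937, 3597, "m1"), "m1")
  expect_equal(r$ratio, 1.7)
  expect_equal(r$n_singleton, 5937L)
  # recessive subgenome, arms: 2,448 vs 3,429
  expect_equal(singletonWgdRatio(mkTable(2448, 3429, "m2"), "m2")$ratio, 0.7)
  # pericentromeric examples: 2,131 vs 981 and 1,038 vs 1,149
  expect_equal(singletonWgdRatio(mkTable(2131, 981, "m1"), "m1")$ratio, 2.2)
  expect_equal(singletonWgdRatio(mkTable(1038, 1149, "m2"), "m2")$ratio, 0.9)
  # degenerate cases
  expect_equal(singletonWgdRatio(mkTable(0, 10, "m1"), "m1")$ratio, 0)
  expect_true(is.na(singletonWgdRatio(mkTable(5, 0, "m1"), "m1")$ratio))
})

test_that("retention rate follows the block bookkeeping formula", {
  expect_equal(retentionRate(2, 1, 3, "m1"), 5 / 6)
  expect_equal(retentionRate(2, 1, 3, "m2"), 4 / 6)
  # no partner loss -> full retention
  expect_equal(retentionRate(4, 0, 6, "m1"), 1)
  expect_true(is.na(retentionRate(0, 0, 0, "m1")))
  # aggregate arm-arm counts: 4,232 + 2,877 over 4,232 + 1,866 + 2,877
  expect_equal(round(retentionRate(4232, 1866, 2877, "m1"), 3), 0.792)
})

test_that("blocks are maximal runs sharing a chromosome pairing", {
  part <- toyPartition(chroms = c("c1", "c2", "c3", "c4"))
  # 12 planted blocks of 6 pairs each, alternating chromosome pairings
  nBlk <- 12L; per <- 6L
  m1ch <- rep(rep(c("c1", "c2"), each = 3), 2)[seq_len(nBlk)]
  m2ch <- rep(c("c3", "c4"), 6)[seq_len(nBlk)]
  rows <- list(); chroms <- character(); pos <- numeric()
  gidx <- 0L
  for (b in seq_len(nBlk)) for (i in seq_len(per)) {
    gidx <- gidx + 1L
    g1 <- sprintf("g1_%03d", gidx); g2 <- sprintf("g2_%03d", gidx)
    rows[[gidx]] <- data.frame(
      m1_gene = g1, m2_gene = g2,
      sorghum_gene = sprintf("s%03d", gidx),
      tandem = FALSE, ks = 0.7, omega = 0.3, status = "pair")
    chroms <- c(chroms, m1ch[b], m2ch[b])
    pos <- c(pos, rep(1e5 + gidx * 5e4, 2))
  }
  genes <- GenomicRanges::GRanges(chroms,
                                  IRanges::IRanges(pos, width = 1e3))
  names(genes) <- as.vector(rbind(sprintf("g1_%03d", seq_len(gidx)),
                                  sprintf("g2_%03d", seq_len(gidx))))
  tb <- assignCategory(do.call(rbind, rows), genes, part)
  bl <- buildBlocks(tb, genes)
  expect_equal(nrow(bl$blocks), nBlk)
  expect_equal(unique(bl$blocks$n_pairs), per)
  # a short run (< 5 genes per side) is excluded
  bl4 <- buildBlocks(tb[1:4, ], genes)
  expect_equal(nrow(bl4$blocks), 0L)
  # a single contiguous run forms one block pair; a trailing 2-gene run
  # on a new pairing is dropped
  bl8 <- buildBlocks(tb[1:8, ], genes)
  expect_equal(nrow(bl8$blocks), 1L)
  expect_equal(nrow(buildBlocks(tb[1:6, ], genes)$blocks), 1L)
})

test_that("block statistics recover planted TE content exactly", {
  part <- toyPartition(chroms = c("c1", "c2"))
  n <- 6L
  g1 <- sprintf("x%d", seq_len(n)); g2 <- sprintf("y%d", seq_len(n))
  genes <- GenomicRanges::GRanges(
    rep(c("c1", "c2"), each = n),
    IRanges::IRanges(rep(1e6 + seq_len(n) * 1e5, 2), width = 1e3))
  names(genes) <- c(g1, g2)
  tb <- data.frame(m1_gene = g1, m2_gene = g2,
                   sorghum_gene = sprintf("s%d", seq_len(n)),
                   tandem = FALSE, ks = 0.7, omega = 0.3, status = "pair")
  tb <- assignCategory(tb, genes, part)
  bl <- buildBlocks(tb, genes)
  expect_equal(nrow(bl$blocks), 1L)
  # plant two disjoint TEs wholly inside the maize1 block interval
  tes <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(1.15e6, 1.32e6), width = c(2e4, 3e4)),
    class = c("LTR", "DNA"))
  st <- blockStats(bl$blocks, bl$members, genes, tes)
  expect_equal(st$te_mb_m1, 5e4 / 1e6)
  expect_equal(st$te_LTR_mb_m1, 2e4 / 1e6)
  expect_equal(st$te_DNA_mb_m1, 3e4 / 1e6)
  expect_equal(st$te_mb_m2, 0)
  # density: 6 genes over the block span
  span <- (max(GenomicRanges::start(genes[g1])) + 1e3 - 1 -
             min(GenomicRanges::start(genes[g1]))) / 1e6
  expect_equal(st$gene_density_m1, 6 / st$size_mb_m1)
})

test_that("status bookkeeping conserves genes on the synthetic dataset", {
  ds <- sharedDataset()
  syn <- ds$syntelogs
  status <- ifelse(!is.na(syn$m1_gene) & !is.na(syn$m2_gene), "pair",
            ifelse(!is.na(syn$m1_gene), "singleton_m1", "singleton_m2"))
  expect_equal(sum(status == "pair") + sum(status != "pair"),
               ds$truth$n_ancestral)
  expect_equal(2 * sum(status == "pair") + sum(status != "pair"),
               length(ds$genes))
  expect_equal(sum(status == "singleton_m1"), ds$truth$n_singleton_m1)
  # with more maize2 loss planted, maize1 singletons dominate
  expect_gt(sum(status == "singleton_m1"), sum(status == "singleton_m2"))
})
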