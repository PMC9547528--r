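mkGenes <- function(starts, width = 2000, strand = "+", chrom = "chr1") {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, width = width),
                              strand = strand)
  names(g) <- paste0("g", seq_along(g))
  g
}

test_that("nearest TE distance is edge-to-edge with overlap = 0", {
  genes <- mkGenes(10001)
  # overlapping TE
  expect_equal(nearestTeDistance(genes, GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(10500, 10600))), 0)
  # TE ending 500 bp before the gene start
  expect_equal(nearestTeDistance(genes, GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(9000, 9500))), 500)
  # minimum of upstream 300 and downstream 200
  tes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(9500, 12201), c(9700, 12500)))
  expect_equal(nearestTeDistance(genes, tes), 200)
  # no TE on the chromosome
  expect_true(is.na(nearestTeDistance(
    genes, GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 10)))))
})

test_that("flank geometry gives 191 windows per side", {
  genes <- mkGenes(c(10001, 30001))
  prof <- teProportionProfile(genes, GenomicRanges::GRanges(),
                              chromLengths = c(chr1 = 1e5))
  expect_equal(sum(prof$part == "upstream"), 191L)
  expect_equal(sum(prof$part == "downstream"), 191L)
  expect_true(all(prof$mean == 0))
  expect_true(all(prof$n_genes == 2))
  # fully TE-covered flanks -> proportion 1 in every window
  teAll <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e5))
  prof2 <- teProportionProfile(genes, teAll, chromLengths = c(chr1 = 1e5))
  expect_true(all(prof2$mean == 1))
  expect_error(teProportionProfile(GenomicRanges::GRanges(),
                                   teAll, chromLengths = c(chr1 = 1e5)),
               "empty")
})

test_that("TP10M normalisation matches its definition and scales linearly", {
  genes <- mkGenes(10001)
  # 12 reads at one position 150 bp upstream of the TSS, library 6e6
  tr <- signalTrack("sirna",
                    data.frame(chrom = "chr1", pos = 9851, count = 12),
                    libraryTotal = 6e6, binWidth = 1L)
  prof <- sirnaProfile(tr, genes, chromLengths = c(chr1 = 1e5))
  up <- prof[prof$part == "upstream", ]
  # every 100-bp window containing position -150 sees 12e7/6e6 = 20 TP10M
  expect_equal(max(up$mean), 20)
  expect_true(all(up$mean %in% c(0, 20)))
  expect_equal(sum(up$mean == 20), 10L)  # 100/10 covering windows
  # linearity in counts
  tr2 <- signalTrack("sirna",
                     data.frame(chrom = "chr1", pos = 9851, count = 36),
                     libraryTotal = 6e6, binWidth = 1L)
  prof2 <- sirnaProfile(tr2, genes, chromLengths = c(chr1 = 1e5))
  expect_equal(max(prof2$mean), 60)
  # empty track -> zero profile
  tr0 <- signalTrack("sirna",
                     data.frame(chrom = character(0), pos = integer(0),
                                count = integer(0)),
                     libraryTotal = 6e6, binWidth = 1L)
  expect_true(all(sirnaProfile(tr0, genes,
                               chromLengths = c(chr1 = 1e5))$mean == 0))
  expect_error(sirnaProfile(signalTrack("sirna",
    data.frame(chrom = "chr1", pos = 1, count = 1), libraryTotal = -1),
    genes), "library")
})

test_that("weighted methylation is the ratio of summed read calls", {
  genes <- mkGenes(10001, width = 4000)
  # two cytosines inside one 50-bp upstream window: 4 methylated / 16 total
  meth <- data.frame(chrom = "chr1", pos = c(9901, 9921),
                     context = "CHH",
                     methylated_reads = c(2, 2), total_reads = c(8, 8))
  tr <- signalTrack("methylation", meth)
  prof <- methylationProfile(tr, genes, "CHH",
                             chromLengths = c(chr1 = 1e5))
  up <- prof[prof$part == "upstream", ]
  expect_equal(sum(up$part == "upstream"), 40L)  # 2 kb / 50 bp
  expect_equal(up$mean[up$n_genes > 0], 0.25)
  # windows without covered cytosines are excluded, not zero
  expect_true(all(up$n_genes[is.nan(up$mean)] == 0))
  # fully methylated window
  meth2 <- transform(meth, methylated_reads = total_reads)
  prof2 <- methylationProfile(signalTrack("methylation", meth2), genes,
                              "CHH", chromLengths = c(chr1 = 1e5))
  up2 <- prof2[prof2$part == "upstream", ]
  expect_equal(up2$mean[up2$n_genes > 0], 1)
  # gene body has 40 bins and values stay in [0, 1]
  expect_equal(sum(prof$part == "body"), 40L)
  ok <- prof$mean[!is.nan(prof$mean)]
  expect_true(all(ok >= 0 & ok <= 1))
})

test_that("gene-body bins span k*L/40 boundaries", {
  # gene of 4000 bp: bin k covers [k*100, (k+1)*100)
  genes <- mkGenes(10001, width = 4000)
  # one fully methylated cytosine in bin 5 (positions 10401..10500)
  meth <- data.frame(chrom = "chr1", pos = 10450, context = "CHH",
                     methylated_reads = 5, total_reads = 5)
  prof <- methylationProfile(signalTrack("methylation", meth), genes,
                             "CHH", chromLengths = c(chr1 = 1e5))
  body <- prof[prof$part == "body", ]
  expect_equal(which(!is.nan(body$mean)), 5L)
  expect_equal(body$mean[5], 1)
})

test_that("histone signal is log2 of pseudocounted treat/input", {
  genes <- mkGenes(10001, width = 2000)
  grid <- seq(7001, 15001, by = 100)
  # treat = input everywhere -> flat zero
  tr <- signalTrack("histone", data.frame(
    chrom = "chr1", pos = grid, treat_count = 5, input_count = 5),
    binWidth = 100L)
  prof <- histoneProfile(tr, genes = genes, chromLengths = c(chr1 = 1e5))
  expect_true(all(prof$mean == 0))
  # treat 7 vs input 3 -> log2(8/4) = 1
  tr2 <- signalTrack("histone", data.frame(
    chrom = "chr1", pos = grid, treat_count = 7, input_count = 3),
    binWidth = 100L)
  prof2 <- histoneProfile(tr2, genes = genes, chromLengths = c(chr1 = 1e5))
  fl2 <- prof2[prof2$part != "body", ]
  expect_true(all(abs(fl2$mean - 1) < 1e-12))
  # body bins smaller than the track grid may be empty (0/0 -> 0)
  expect_true(all(prof2$mean[prof2$part == "body"] %in% c(0, 1)))
  # absent counts behave as 0/0 -> log2(1) = 0
  tr3 <- signalTrack("histone", data.frame(
    chrom = character(0), pos = integer(0), treat_count = integer(0),
    input_count = integer(0)), binWidth = 100L)
  prof3 <- histoneProfile(tr3, genes = genes, chromLengths = c(chr1 = 1e5))
  expect_true(all(prof3$mean == 0))
})

test_that("strand flip leaves the profile of a symmetric track unchanged", {
  set.seed(11)
  starts <- seq(20001, 80001, by = 10000)
  gPlus <- mkGenes(starts, width = 3000)
  gMinus <- mkGenes(starts, width = 3000, strand = "-")
  tr <- signalTrack("sirna", data.frame(
    chrom = "chr1", pos = seq(1, 1e5, by = 7), count = 2),
    libraryTotal = 1e7, binWidth = 1L)
  pPlus <- sirnaProfile(tr, gPlus, chromLengths = c(chr1 = 1e5))
  pMinus <- sirnaProfile(tr, gMinus, chromLengths = c(chr1 = 1e5))
  # a uniform track is strand-symmetric: aggregate profiles agree
  expect_equal(mean(pPlus$mean), mean(pMinus$mean), tolerance = 1e-2)
  expect_equal(pPlus$mean[pPlus$part == "upstream"],
               rev(pMinus$mean[pMinus$part == "downstream"]),
               tolerance = 0.1)
})

test_that("planted siRNA and CHH islands are recovered at their offsets", {
  cfg <- simConfig(seed = 17L)
  genes <- mkGenes(seq(30001, 330001, by = 10000), width = 2000)
  S4Vectors::mcols(genes)$subgenome <- "m1"
  set.seed(17)
  tr <- generateTrack("sirna", genes, cfg)
  prof <- sirnaProfile(tr, genes, chromLengths = c(chr1 = 4e5))
  up <- prof[prof$part == "upstream", ]
  # peak centred islandOffset upstream of the TSS: the best window starts
  # about offset + window/2 before the TSS
  best <- up$offset[which.max(up$mean)]
  expect_lt(abs(best - (-cfg@islandOffset - 50)), 100)
  set.seed(18)
  mtr <- generateTrack("methylation", genes, cfg)
  mprof <- methylationProfile(mtr, genes, "CHH",
                              chromLengths = c(chr1 = 4e5))
  mup <- mprof[mprof$part == "upstream", ]
  mbest <- mup$offset[which.max(mup$mean)]
  expect_lt(abs(mbest - (-cfg@islandOffset - 25)), 150)
  # and a zero-height island gives a flat background
  cfg0 <- simConfig(seed = 19L, chhIslandHeight = 0)
  set.seed(19)
  m0 <- generateTrack("methylation", genes, cfg0)
  p0 <- methylationProfile(m0, genes, "CHH", chromLengths = c(chr1 = 4e5))
  v <- p0$mean[!is.nan(p0$mean)]
  expect_lt(max(abs(v - 0.05)), 0.04)
})
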