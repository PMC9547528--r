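test_that("window arithmetic gives one record per 1 Mb/500 kb window", {
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, width = 10))
  ws <- windowStats(g, GenomicRanges::GRanges(), c(chr1 = 10e6))
  expect_equal(nrow(ws), 19L)  # floor((10 - 1) / 0.5) + 1
  expect_equal(ws$window_start, seq(0, 9e6, by = 5e5))
})

test_that("densities are zero without features and saturate with them", {
  ws <- windowStats(GenomicRanges::GRanges(), GenomicRanges::GRanges(),
                    c(chr1 = 3e6))
  expect_true(all(ws$gene_density == 0))
  expect_true(all(ws$repeat_length == 0))
  # a window fully covered by one repeat has repeat_length 1
  rep1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 3e6))
  ws2 <- windowStats(GenomicRanges::GRanges(), rep1, c(chr1 = 3e6))
  expect_equal(ws2$repeat_length, rep(1, nrow(ws2)))
})

test_that("genes are counted by start position", {
  # gene starting in window 1 but ending in window 3
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2e5, 1.6e6))
  ws <- windowStats(g, GenomicRanges::GRanges(), c(chr1 = 2e6))
  expect_equal(ws$gene_density[1], 1)   # [0, 1e6)
  expect_equal(ws$gene_density[2], 0)   # [5e5, 1.5e6): start not inside
})

test_that("negative coordinates are rejected", {
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(0, 10))
  expect_error(windowStats(g, GenomicRanges::GRanges(), c(chr1 = 1e6)),
               "coordinates")
})

test_that("recombination rates are piecewise marker slopes", {
  m <- data.frame(chrom = "chr1", bp = c(0, 2e6), cM = c(0, 4))
  rm <- recombinationRate(m)
  expect_equal(recombRateAt(rm, "chr1", c(1e5, 1e6, 1.9e6)), rep(2, 3))
  # flat cM -> rate 0
  m2 <- data.frame(chrom = "chr1", bp = c(0, 1e6, 2e6), cM = c(0, 0, 1))
  expect_equal(recombRateAt(recombinationRate(m2), "chr1", 5e5), 0)
  # piecewise slope: (0,0), (1 Mb,1), (3 Mb,1.5) -> rate at 2 Mb = 0.25
  m3 <- data.frame(chrom = "chr1", bp = c(0, 1e6, 3e6), cM = c(0, 1, 1.5))
  expect_equal(recombRateAt(recombinationRate(m3), "chr1", 2e6), 0.25)
  # decreasing cM is a map inconsistency
  m4 <- data.frame(chrom = "chr1", bp = c(0, 1e6), cM = c(1, 0))
  expect_error(recombinationRate(m4), "decreasing")
})

test_that("segmentation recovers a constructed low-recombination block", {
  part <- toyPartition(chroms = "chrA")
  peri <- partitionRanges(part, "peri")
  expect_equal(length(peri), 1L)
  # constructed peri is [4e6, 6e6]; recovery to window resolution
  expect_lt(abs(GenomicRanges::start(peri) - 4e6), 1.1e6)
  expect_lt(abs(GenomicRanges::end(peri) - 6e6), 1.1e6)
  # partition tiles the chromosome
  p <- partitionRanges(part)
  expect_equal(sum(GenomicRanges::width(p)), 10e6)
  expect_true(validObject(part))
})

test_that("thresholds admitting all windows degenerate to whole-chromosome peri", {
  track <- data.table::data.table(
    chrom = "chrA", window_start = seq(0, 9e6, 5e5),
    window_end = seq(0, 9e6, 5e5) + 1e6,
    gene_density = 1, repeat_length = 0.9, recombination = 0.01)
  cen <- GenomicRanges::GRanges("chrA", IRanges::IRanges(5e6, 5.01e6))
  expect_warning(
    part <- segmentGenome(track, cen, c(chrA = 10e6), rMax = 100,
                          tMin = 0),
    "whole chromosome")
  expect_equal(sum(GenomicRanges::width(partitionRanges(part, "peri"))),
               10e6)
  expect_equal(length(partitionRanges(part, "arm")), 0L)
})

test_that("explicit boundaries override the threshold rule", {
  track <- data.table::data.table(
    chrom = "chrA", window_start = seq(0, 9e6, 5e5),
    window_end = seq(0, 9e6, 5e5) + 1e6,
    gene_density = 1, repeat_length = 0.5, recombination = 0.5)
  cen <- GenomicRanges::GRanges("chrA", IRanges::IRanges(5e6, 5.01e6))
  part <- segmentGenome(track, cen, c(chrA = 10e6),
                        boundaries = data.frame(chrom = "chrA",
                                                peri_start = 3e6,
                                                peri_end = 7e6))
  peri <- partitionRanges(part, "peri")
  expect_equal(GenomicRanges::start(peri), 3e6 + 1)
  expect_equal(GenomicRanges::end(peri), 7e6)
})

test_that("features are classified by their midpoint", {
  part <- toyPartition(chroms = "chrA")
  peri <- partitionRanges(part, "peri")
  ps <- GenomicRanges::start(peri); pe <- GenomicRanges::end(peri)
  g <- GenomicRanges::GRanges("chrA", IRanges::IRanges(
    c(1e5,                 # wholly in arm1
      ps + 1e5,            # wholly in peri
      ps - 900),           # straddles boundary, midpoint inside peri
    width = c(1e3, 1e3, 2e3)))
  expect_equal(classifyRegion(g, part), c("arm", "peri", "peri"))
  # unknown chromosome errors
  bad <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 10))
  expect_error(classifyRegion(bad, part), "absent")
})

test_that("synthetic genome peri fraction is recovered by segmentation", {
  res <- sharedPipeline()
  part <- res$partition
  cfg <- sharedConfig()
  for (ch in unique(as.character(GenomicRanges::seqnames(
      partitionRanges(part))))) {
    peri <- partitionRanges(part, "peri")
    peri <- peri[as.character(GenomicRanges::seqnames(peri)) == ch]
    expected <- cfg@periFraction * cfg@chromLength
    # within 2 windows of the configured peri length
    expect_lt(abs(sum(GenomicRanges::width(peri)) - expected), 2e6)
  }
  # recombination is suppressed in the recovered peri
  ds <- sharedDataset()
  rm <- recombinationRate(ds$markers)
  g <- ds$genes
  reg <- classifyRegion(g, part)
  rate <- recombRateAt(rm, as.character(GenomicRanges::seqnames(g)),
                       GenomicRanges::start(g))
  expect_lt(mean(rate[reg == "peri"]), mean(rate[reg == "arm"]))
})
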