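# Shared synthetic dataset, generated once per test run.  Small enough to
# keep the suite fast but large enough for direction-recovery checks.

.fixtureEnv <- new.env(parent = emptyenv())

sharedConfig <- function() {
  simConfig(seed = 101L, nChromosomes = 2L, chromLength = 10e6,
            geneDensityArm = 55, geneDensityPeri = 20, nTissues = 6L,
            nBlocksPerChrom = 4L, cdsCodons = 120L, nPanel = 12L)
}

sharedDatasetDir <- function() {
  if (is.null(.fixtureEnv$dir)) {
    d <- file.path(tempdir(), "subfrac-shared-ds")
    if (!file.exists(file.path(d, "manifest.tsv")))
      generateDataset(sharedConfig(), d)
    .fixtureEnv$dir <- d
  }
  .fixtureEnv$dir
}

sharedDataset <- function() {
  if (is.null(.fixtureEnv$ds))
    .fixtureEnv$ds <- readDataset(sharedDatasetDir())
  .fixtureEnv$ds
}

sharedPipeline <- function() {
  if (is.null(.fixtureEnv$res))
    .fixtureEnv$res <- suppressWarnings(runPipeline(sharedDatasetDir()))
  .fixtureEnv$res
}

# a simple two-chromosome partition for unit tests: peri = [4e6, 6e6]
toyPartition <- function(chroms = c("chrA", "chrB"), L = 10e6,
                         periStart = 4e6, periEnd = 6e6) {
  track <- data.table::rbindlist(lapply(chroms, function(ch) {
    starts <- seq(0, L - 1e6, by = 5e5)
    mids <- starts + 5e5
    data.table::data.table(
      chrom = ch, window_start = starts, window_end = starts + 1e6,
      gene_density = 10,
      repeat_length = ifelse(mids > periStart & mids <= periEnd, 0.7, 0.2),
      recombination = ifelse(mids > periStart & mids <= periEnd, 0.1, 3))
  }))
  cen <- GenomicRanges::GRanges(chroms,
    IRanges::IRanges(rep((periStart + periEnd) / 2, length(chroms)),
                     width = 1e4))
  segmentGenome(track, cen, setNames(rep(L, length(chroms)), chroms))
}
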