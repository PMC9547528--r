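tinyConfig <- function(seed = 5L, ...)
  simConfig(seed = seed, nChromosomes = 1L, chromLength = 4e6,
            geneDensityArm = 30, geneDensityPeri = 12, nTissues = 3L,
            nBlocksPerChrom = 2L, cdsCodons = 40L, nPanel = 6L, ...)

test_that("invalid configurations are rejected with the field named", {
  expect_error(simConfig(periFraction = 1.2), "periFraction")
  expect_error(simConfig(lossProb = c(m1_arm = -0.1, m1_peri = 0.2,
                                      m2_arm = 0.5, m2_peri = 0.5)),
               "lossProb")
  expect_error(simConfig(lossProb = c(m1_arm = 0.6, m1_peri = 0.2,
                                      m2_arm = 0.6, m2_peri = 0.5)),
               "sum")
  expect_error(simConfig(synRate = c(bad = 1)), "synRate")
  expect_error(simConfig(dominanceEffect = 0.5), "dominanceEffect")
  expect_error(simConfig(notAField = 1), "unknown")
})

test_that("generation is byte-identical under a fixed seed", {
  d1 <- file.path(tempdir(), "subfrac-det1")
  d2 <- file.path(tempdir(), "subfrac-det2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generateDataset(tinyConfig(), d1)
  m2 <- generateDataset(tinyConfig(), d2)
  expect_identical(m1, m2)
  for (f in m1$file) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # a different seed changes the data
  d3 <- file.path(tempdir(), "subfrac-det3")
  unlink(d3, recursive = TRUE)
  generateDataset(tinyConfig(seed = 6L), d3)
  expect_false(identical(tools::md5sum(file.path(d1, "fpkm.tsv"))[[1]],
                         tools::md5sum(file.path(d3, "fpkm.tsv"))[[1]]))
})

test_that("the no-loss limit yields only retained pairs", {
  d <- file.path(tempdir(), "subfrac-noloss")
  unlink(d, recursive = TRUE)
  generateDataset(tinyConfig(lossProb = c(m1_arm = 0, m1_peri = 0,
                                          m2_arm = 0, m2_peri = 0)), d)
  syn <- data.table::fread(file.path(d, "syntelogs.tsv"),
                           na.strings = c("", "NA"))
  expect_true(all(!is.na(syn$m1_gene) & !is.na(syn$m2_gene)))
})

test_that("manifest record counts match the files on disk", {
  d <- sharedDatasetDir()
  man <- data.table::fread(file.path(d, "manifest.tsv"))
  syn <- data.table::fread(file.path(d, "syntelogs.tsv"))
  expect_equal(man[man$file == "syntelogs.tsv", ]$records, nrow(syn))
  fa <- Biostrings::readDNAStringSet(file.path(d, "maize_cds.fa"))
  expect_equal(man[man$file == "maize_cds.tsv" |
                     man$file == "maize_cds.fa", ]$records, length(fa))
  gff <- rtracklayer::import(file.path(d, "genes.gff3"))
  expect_equal(man[man$file == "genes.gff3", ]$records, length(gff))
  # retained CDS and annotation agree gene-by-gene
  expect_setequal(names(fa), gff$ID)
})

test_that("generated sequences recover the planted substitution rates", {
  ds <- sharedDataset()
  cfg <- sharedConfig()
  syn <- ds$syntelogs
  pairs <- syn[!is.na(syn$m1_gene) & !is.na(syn$m2_gene), ]
  seqs <- c(as.character(ds$maizeCds), as.character(ds$sorghumCds))
  kk1 <- ng86Table(seqs, data.frame(id1 = pairs$m1_gene,
                                    id2 = pairs$sorghum_gene))
  kk2 <- ng86Table(seqs, data.frame(id1 = pairs$m2_gene,
                                    id2 = pairs$sorghum_gene))
  # maize2 evolves faster nonsynonymously by construction
  expect_gt(mean(kk2$ka, na.rm = TRUE), mean(kk1$ka, na.rm = TRUE))
  tt <- pairedT(kk2$ka, kk1$ka)
  expect_lt(tt$p.value, 0.01)
  # rates are within a third of the configured per-branch values
  expect_lt(abs(mean(kk1$ka, na.rm = TRUE) -
                  mean(cfg@nonsynRate[c("m1_arm", "m1_peri")])),
            mean(cfg@nonsynRate) / 3)
})

test_that("unknown track kinds are rejected and tracks carry their schema", {
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(20001, width = 1000))
  names(genes) <- "g"
  cfg <- tinyConfig()
  expect_error(generateTrack("junk", genes, cfg))
  expect_error(generateTrack("sirna", GenomicRanges::GRanges(), cfg),
               "non-empty")
  tr <- generateTrack("methylation", genes, cfg)
  expect_s4_class(tr, "SignalTrack")
  d <- trackData(tr)
  expect_true(all(d$methylated_reads <= d$total_reads))
  expect_true(all(d$context %in% c("CG", "CHG", "CHH")))
  his <- generateTrack("histone", genes, cfg)
  expect_true(all(c("treat_count", "input_count") %in%
                    names(trackData(his))))
  sir <- generateTrack("sirna", genes, cfg)
  expect_gt(libraryTotal(sir), 0)
})

test_that("signal track validity catches malformed data", {
  expect_error(signalTrack("sirna", data.frame(chrom = "c", pos = 1,
                                               count = 1)),
               "libraryTotal")
  expect_error(signalTrack("methylation",
                           data.frame(chrom = "c", pos = 1, context = "XX",
                                      methylated_reads = 1,
                                      total_reads = 2)),
               "context")
  expect_error(signalTrack("methylation",
                           data.frame(chrom = "c", pos = 1, context = "CG",
                                      methylated_reads = 3,
                                      total_reads = 2)),
               "methylated_reads")
})

test_that("dataset round-trips through the readers", {
  ds <- sharedDataset()
  expect_s4_class(ds$genes, "GRanges")
  expect_true(!is.null(names(ds$genes)))
  expect_s4_class(ds$sirna, "SignalTrack")
  expect_equal(ds$sirna@kind, "sirna")
  expect_true(is.finite(libraryTotal(ds$sirna)))
  expect_true(all(c("LTR", "DNA") %in% S4Vectors::mcols(ds$tes)$class))
  expect_equal(nrow(ds$fpkm), length(ds$genes))
  expect_true(all(rownames(ds$panel) %in% ds$snps$snp_id))
})
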