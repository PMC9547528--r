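# Readers for the dataset directory layout written by generateDataset()
# (and for equivalently formatted real data).

#' Read a signal track file
#'
#' Tab-separated position tables; siRNA tracks carry a
#' `# library_total=N` comment header giving the mapped-library size.
#'
#' @param path file path.
#' @param kind `"sirna"`, `"methylation"` or `"histone"`.
#' @param binWidth bin width of the positions (default: 10 for sirna, 1
#'   for methylation, 100 for histone, matching the generator's output).
#' @return a [SignalTrack-class].
#' @export
readSignalTrack <- function(path, kind = c("sirna", "methylation",
                                           "histone"),
                            binWidth = NULL) {
  kind <- match.arg(kind)
  if (is.null(binWidth))
    binWidth <- switch(kind, sirna = 10L, methylation = 1L, histone = 100L)
  lib <- NA_real_
  if (kind == "sirna") {
    first <- readLines(path, n = 1L)
    m <- regmatches(first, regexec("library_total=([0-9.eE+]+)", first))[[1]]
    if (length(m) == 2) lib <- as.numeric(m[2])
  }
  dt <- fread(path, sep = "\t", skip = if (kind == "sirna") 1L else 0L)
  signalTrack(kind, dt, libraryTotal = lib, binWidth = binWidth)
}

#' Read a generated (or equivalently laid out) dataset directory
#'
#' @param dir the dataset directory (see [generateDataset()] for the
#'   files and their formats).
#' @param tracks also load the signal tracks (default TRUE; they are the
#'   largest files).
#' @return a named list: `genes` (named `GRanges`), `tes` (`GRanges` with
#'   `class`), `markers`, `syntelogs`, `sorghumCds`, `maizeCds`
#'   (`DNAStringSet`), `fpkm`, `protein` (matrices), `snps`, `panel`
#'   (matrix), `acrs` (`GRanges` with `acr_id`, `score`), `homology`,
#'   `loops`, `chromLengths`, `truth`, and the tracks `sirna`,
#'   `methylation`, `histone`.
#' @export
readDataset <- function(dir, tracks = TRUE) {
  fp <- function(f) file.path(dir, f)
  sizes <- fread(fp("chrom.sizes"), header = FALSE,
                 col.names = c("chrom", "length"))
  chromLengths <- setNames(sizes$length, sizes$chrom)
  genes <- rtracklayer::import(fp("genes.gff3"), format = "GFF3")
  names(genes) <- mcols(genes)$ID
  GenomeInfoDb::seqlevels(genes) <- names(chromLengths)
  GenomeInfoDb::seqlengths(genes) <- chromLengths
  tes <- rtracklayer::import(fp("tes.bed"), format = "BED")
  mcols(tes)$class <- mcols(tes)$name
  acrsDt <- fread(fp("acrs.bed"), header = FALSE,
                  col.names = c("chrom", "start", "end", "acr_id", "score"))
  acrs <- GRanges(acrsDt$chrom,
                  IRanges(acrsDt$start + 1L, acrsDt$end),
                  acr_id = acrsDt$acr_id, score = acrsDt$score,
                  seqlengths = chromLengths)
  panelDt <- fread(fp("panel.tsv"))
  panel <- as.matrix(panelDt[, -1])
  rownames(panel) <- panelDt$snp_id
  readMatrix <- function(f) {
    d <- fread(fp(f))
    m <- as.matrix(d[, -1])
    rownames(m) <- d$gene
    m
  }
  out <- list(
    genes = genes, tes = tes,
    markers = fread(fp("markers.tsv")),
    syntelogs = fread(fp("syntelogs.tsv"), na.strings = c("", "NA")),
    sorghumCds = Biostrings::readDNAStringSet(fp("sorghum_cds.fa")),
    maizeCds = Biostrings::readDNAStringSet(fp("maize_cds.fa")),
    fpkm = readMatrix("fpkm.tsv"),
    protein = readMatrix("protein.tsv"),
    snps = fread(fp("snps.tsv")),
    panel = panel,
    acrs = acrs,
    homology = fread(fp("acr_homology.tsv"), na.strings = c("", "NA")),
    loops = fread(fp("loops.bedpe"), header = FALSE,
                  col.names = c("chrom1", "start1", "end1",
                                "chrom2", "start2", "end2")),
    chromLengths = chromLengths,
    truth = jsonlite::read_json(fp("truth.json"), simplifyVector = TRUE))
  if (tracks) {
    out$sirna <- readSignalTrack(fp("sirna.tsv"), "sirna")
    out$methylation <- readSignalTrack(fp("methylation.tsv"), "methylation")
    out$histone <- readSignalTrack(fp("histone.tsv"), "histone")
  }
  out
}
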