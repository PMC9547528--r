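#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps distanceToNearest granges
#' @importFrom IRanges IRanges ranges overlapsAny
#' @importFrom data.table data.table as.data.table setnames rbindlist fread
#'   fwrite setorder := fifelse copy setDT setorderv dcast melt
NULL

## quiet R CMD check for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "chrom", "pos", "cM", "bp", "rate", "window_start",
  "window_end", "gene_density", "repeat_length", "recombination", "status",
  "category", "tandem", "ks", "omega", "m1_region", "m2_region", "block",
  "m1_chrom", "m2_chrom", "m1_gene", "m2_gene", "sorghum_gene", "reason",
  "tissue", "call", "side", "offset", "value", "n_genes", "context",
  "methylated_reads", "total_reads", "count", "treat_count", "input_count",
  "gerp", "class", "snp_id", "gene", "region", "subgenome", "acr_id",
  "partner_acr", "sorghum_acr", "near_status", "dist_class", "idx", "win"
))

# ---------------------------------------------------------------------------
# SimConfig
# ---------------------------------------------------------------------------

#' Configuration for the synthetic two-subgenome dataset generator
#'
#' A `SimConfig` holds every tunable parameter of the synthetic
#' paleotetraploid genome: chromosome geometry, gene/TE density contrasts
#' between chromosomal arms and pericentromeric regions, per-subgenome and
#' per-region gene-loss probabilities, substitution rates, the expression
#' dominance effect, flanking CHH/siRNA island shape, and ACR retention
#' probabilities.  Probability maps are length-4 named numeric vectors with
#' names `m1_arm`, `m1_peri`, `m2_arm`, `m2_peri`.
#'
#' @slot seed integer RNG seed; identical config + seed gives byte-identical
#'   output files.
#' @slot nChromosomes integer, chromosomes per subgenome.
#' @slot chromLength numeric, chromosome length in bp.
#' @slot periFraction numeric in (0,1), fraction of each chromosome occupied
#'   by the pericentromeric region.
#' @slot geneDensityArm,geneDensityPeri numeric, genes per Mb.
#' @slot teDensityArm,teDensityPeri numeric in \[0,1\], fraction of bp covered
#'   by transposable elements.
#' @slot lossProb named numeric(4), probability that the homoeolog of the
#'   given subgenome is deleted when it lies in the given region.  Losses of
#'   the two copies of a pair are drawn mutually exclusively, so
#'   `lossProb[m1_*] + lossProb[m2_*] <= 1` is required.
#' @slot synRate,nonsynRate named numeric(4), expected substitutions per
#'   synonymous / nonsynonymous site on the branch from the common ancestor.
#' @slot dominanceEffect numeric >= 1, multiplicative FPKM factor applied to
#'   the maize1 copy of dominance-affected pairs.
#' @slot dominanceFraction numeric in \[0,1\], fraction of pairs with a
#'   maize1 copy in a chromosomal arm that receive the dominance effect.
#' @slot exprNoiseSd numeric, sd of per-tissue log-normal expression noise
#'   (0 gives a noise-free matrix).
#' @slot chhIslandHeight numeric in \[0,1\], CHH methylation level at the
#'   flanking island peaks (background is 0.05); the maize2 islands are
#'   scaled by `m2IslandFactor`.
#' @slot m2IslandFactor numeric >= 1, relative height of maize2 siRNA/CHH
#'   islands.
#' @slot islandOffset numeric, distance in bp of the island peak from the
#'   TSS (upstream) and TTS (downstream).
#' @slot acrRetentionProb named numeric(4), probability that the ACR of a
#'   retained gene copy is itself retained.
#' @slot nTissues integer, number of expression columns.
#' @slot nBlocksPerChrom integer, syntenic block pairs planted per
#'   chromosome.
#' @slot cdsCodons integer, codons per coding sequence.
#' @slot tandemProb numeric, fraction of syntelog rows flagged as tandem
#'   duplicates.
#' @slot nPanel integer, individuals in the genotype panel used for genetic
#'   load.
#'
#' @seealso [simConfig()] for the user-facing constructor with defaults,
#'   [generateDataset()].
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  nChromosomes = "integer",
  chromLength = "numeric",
  periFraction = "numeric",
  geneDensityArm = "numeric",
  geneDensityPeri = "numeric",
  teDensityArm = "numeric",
  teDensityPeri = "numeric",
  lossProb = "numeric",
  synRate = "numeric",
  nonsynRate = "numeric",
  dominanceEffect = "numeric",
  dominanceFraction = "numeric",
  exprNoiseSd = "numeric",
  chhIslandHeight = "numeric",
  m2IslandFactor = "numeric",
  islandOffset = "numeric",
  acrRetentionProb = "numeric",
  nTissues = "integer",
  nBlocksPerChrom = "integer",
  cdsCodons = "integer",
  tandemProb = "numeric",
  nPanel = "integer"
))

.RATE_KEYS <- c("m1_arm", "m1_peri", "m2_arm", "m2_peri")

# put two GRanges on the union of their seqlevels so cross-object
# operations do not warn about disjoint seqinfo
.sameSeqlevels <- function(x, y) {
  u <- union(GenomeInfoDb::seqlevels(x), GenomeInfoDb::seqlevels(y))
  suppressWarnings({
    GenomeInfoDb::seqlevels(x) <- u
    GenomeInfoDb::seqlevels(y) <- u
  })
  list(x, y)
}

.checkRateMap <- function(x, what, probs = TRUE) {
  if (!identical(sort(names(x)), sort(.RATE_KEYS)))
    return(sprintf("'%s' must be named %s", what,
                   paste(.RATE_KEYS, collapse = ", ")))
  if (any(!is.finite(x)) || any(x < 0))
    return(sprintf("'%s' must be finite and >= 0", what))
  if (probs && any(x > 1))
    return(sprintf("'%s' entries must be probabilities in [0,1]", what))
  NULL
}

setValidity("SimConfig", function(object) {
  msg <- character()
  chk <- function(cond, m) if (!cond) msg <<- c(msg, m)
  chk(object@periFraction > 0 && object@periFraction < 1,
      "'periFraction' must be in (0,1)")
  chk(object@chromLength > 0, "'chromLength' must be > 0")
  chk(object@nChromosomes >= 1L, "'nChromosomes' must be >= 1")
  chk(all(c(object@geneDensityArm, object@geneDensityPeri) > 0),
      "gene densities must be > 0")
  chk(all(c(object@teDensityArm, object@teDensityPeri) >= 0 &
            c(object@teDensityArm, object@teDensityPeri) <= 1),
      "TE densities must be fractions in [0,1]")
  for (nm in c("lossProb", "acrRetentionProb")) {
    m <- .checkRateMap(slot(object, nm), nm, probs = TRUE)
    if (!is.null(m)) msg <- c(msg, m)
  }
  for (nm in c("synRate", "nonsynRate")) {
    m <- .checkRateMap(slot(object, nm), nm, probs = FALSE)
    if (!is.null(m)) msg <- c(msg, m)
  }
  if (!length(msg) && any(object@lossProb[c("m1_arm", "m1_peri")] +
                            object@lossProb[c("m2_arm", "m2_peri")] > 1))
    msg <- c(msg,
      "'lossProb': m1 + m2 loss probabilities must sum to <= 1 per region")
  chk(object@dominanceEffect >= 1, "'dominanceEffect' must be >= 1")
  chk(object@dominanceFraction >= 0 && object@dominanceFraction <= 1,
      "'dominanceFraction' must be in [0,1]")
  chk(object@chhIslandHeight >= 0 && object@chhIslandHeight <= 1,
      "'chhIslandHeight' must be in [0,1]")
  chk(object@exprNoiseSd >= 0, "'exprNoiseSd' must be >= 0")
  chk(object@nTissues >= 1L, "'nTissues' must be >= 1")
  chk(object@cdsCodons >= 10L, "'cdsCodons' must be >= 10")
  chk(object@nPanel >= 1L, "'nPanel' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig compact parameter listing.
#' @param object a `SimConfig`.
#' @export
setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nChromosomes, "chromosome(s)/subgenome,",
      sprintf("%.1f Mb each, peri fraction %.2f\n",
              object@chromLength / 1e6, object@periFraction))
  cat("  gene density (arm/peri):", object@geneDensityArm, "/",
      object@geneDensityPeri, "per Mb;  TE density:",
      object@teDensityArm, "/", object@teDensityPeri, "\n")
  cat("  loss prob:", paste(sprintf("%s=%.2f", names(object@lossProb),
                                    object@lossProb), collapse = " "), "\n")
  cat("  Ks rate:", paste(sprintf("%s=%.3f", names(object@synRate),
                                  object@synRate), collapse = " "), "\n")
  cat("  Ka rate:", paste(sprintf("%s=%.3f", names(object@nonsynRate),
                                  object@nonsynRate), collapse = " "), "\n")
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# GenomePartition
# ---------------------------------------------------------------------------

#' Arm/pericentromere partition of a genome
#'
#' Per chromosome, the partition is three non-overlapping intervals (arm1,
#' peri, arm2) that tile the chromosome, with the centromere contained in
#' the pericentromeric interval.  The windowed density track the partition
#' was segmented from is carried along in `track`.
#'
#' @slot partition a [GenomicRanges::GRanges] with metadata column `region`
#'   (`arm1`, `peri`, `arm2`) tiling each chromosome.
#' @slot centromere a `GRanges`, one range per chromosome.
#' @slot track a `data.table` of windowed statistics (see [windowStats()]),
#'   possibly with a `recombination` column.
#'
#' @seealso [segmentGenome()], [classifyRegion()]
#' @export
setClass("GenomePartition", representation(
  partition = "GRanges",
  centromere = "GRanges",
  track = "ANY"
))

setValidity("GenomePartition", function(object) {
  p <- object@partition
  if (is.null(mcols(p)$region) ||
      !all(mcols(p)$region %in% c("arm1", "peri", "arm2")))
    return("partition must carry a 'region' column in {arm1, peri, arm2}")
  for (ch in unique(as.character(seqnames(p)))) {
    pp <- p[seqnames(p) == ch]
    pp <- pp[order(start(pp))]
    if (length(pp) > 1 && any(start(pp)[-1] != end(pp)[-length(pp)] + 1L))
      return(sprintf("partition of %s has gaps or overlaps", ch))
    cen <- object@centromere[seqnames(object@centromere) == ch]
    peri <- pp[mcols(pp)$region == "peri"]
    if (length(cen) && length(peri) &&
        !(start(cen) >= start(peri) && end(cen) <= end(peri)))
      return(sprintf("centromere of %s not contained in peri", ch))
  }
  TRUE
})

#' @describeIn GenomePartition summary of the partition.
#' @param object a `GenomePartition`.
#' @export
setMethod("show", "GenomePartition", function(object) {
  p <- object@partition
  chs <- unique(as.character(seqnames(p)))
  cat("GenomePartition over", length(chs), "chromosome(s)\n")
  peri <- p[mcols(p)$region == "peri"]
  cat(sprintf("  peri: %.1f Mb total (%.0f%% of partitioned length)\n",
              sum(width(peri)) / 1e6, 100 * sum(width(peri)) / sum(width(p))))
})

#' Extract the partition ranges
#'
#' @param x a [GenomePartition-class].
#' @param region optional subset, one of `"arm1"`, `"peri"`, `"arm2"`, or
#'   `"arm"` for both arms.
#' @return a `GRanges`.
#' @export
partitionRanges <- function(x, region = NULL) {
  stopifnot(is(x, "GenomePartition"))
  p <- x@partition
  if (is.null(region)) return(p)
  keep <- if (identical(region, "arm")) {
    mcols(p)$region %in% c("arm1", "arm2")
  } else mcols(p)$region == region
  p[keep]
}

#' @rdname partitionRanges
#' @export
centromeres <- function(x) {
  stopifnot(is(x, "GenomePartition"))
  x@centromere
}

#' @rdname partitionRanges
#' @export
densityTrack <- function(x) {
  stopifnot(is(x, "GenomePartition"))
  x@track
}

# ---------------------------------------------------------------------------
# SignalTrack
# ---------------------------------------------------------------------------

#' Per-position signal track (siRNA counts, methylation calls, ChIP counts)
#'
#' A thin S4 container around a position table, keyed by kind:
#' \describe{
#'   \item{sirna}{columns `chrom`, `pos`, `count` plus a `libraryTotal`
#'     (total uniquely and perfectly mapped reads) used for TP10M scaling.}
#'   \item{methylation}{columns `chrom`, `pos`, `context` (CG/CHG/CHH),
#'     `methylated_reads`, `total_reads`.}
#'   \item{histone}{columns `chrom`, `pos`, `treat_count`, `input_count`;
#'     `pos` is the start of a fixed-width bin of `binWidth` bp.}
#' }
#'
#' @slot kind one of `"sirna"`, `"methylation"`, `"histone"`.
#' @slot data a `data.table` as described above.
#' @slot libraryTotal numeric, siRNA library size (NA otherwise).
#' @slot binWidth integer bin width for binned tracks (1 for per-base).
#'
#' @seealso [signalTrack()], [readSignalTrack()], [sirnaProfile()],
#'   [methylationProfile()], [histoneProfile()]
#' @export
setClass("SignalTrack", representation(
  kind = "character",
  data = "ANY",
  libraryTotal = "numeric",
  binWidth = "integer"
))

setValidity("SignalTrack", function(object) {
  kinds <- c("sirna", "methylation", "histone")
  if (!object@kind %in% kinds)
    return(sprintf("kind must be one of %s", paste(kinds, collapse = ", ")))
  d <- object@data
  need <- switch(object@kind,
    sirna = c("chrom", "pos", "count"),
    methylation = c("chrom", "pos", "context", "methylated_reads",
                    "total_reads"),
    histone = c("chrom", "pos", "treat_count", "input_count"))
  if (!all(need %in% names(d)))
    return(sprintf("track data must have columns %s",
                   paste(need, collapse = ", ")))
  if (object@kind == "sirna") {
    if (!is.finite(object@libraryTotal) || object@libraryTotal <= 0)
      return("siRNA tracks need a positive libraryTotal")
    if (nrow(d) && any(d$count < 0)) return("counts must be >= 0")
  }
  if (object@kind == "methylation" && nrow(d)) {
    if (!all(d$context %in% c("CG", "CHG", "CHH")))
      return("context must be CG, CHG or CHH")
    if (any(d$methylated_reads > d$total_reads) ||
        any(d$methylated_reads < 0))
      return("need 0 <= methylated_reads <= total_reads")
  }
  if (object@kind == "histone" && nrow(d) &&
      any(d$treat_count < 0 | d$input_count < 0))
    return("histone counts must be >= 0")
  TRUE
})

#' Construct a SignalTrack
#'
#' @param kind `"sirna"`, `"methylation"` or `"histone"`.
#' @param data a data.frame/data.table with the columns required for `kind`
#'   (see [SignalTrack-class]).
#' @param libraryTotal total mapped-library size (siRNA only).
#' @param binWidth bin width in bp (1 = per-base positions).
#' @return a [SignalTrack-class].
#' @export
signalTrack <- function(kind, data, libraryTotal = NA_real_, binWidth = 1L) {
  new("SignalTrack", kind = kind, data = as.data.table(data),
      libraryTotal = as.numeric(libraryTotal), binWidth = as.integer(binWidth))
}

#' @describeIn SignalTrack brief summary.
#' @param object a `SignalTrack`.
#' @export
setMethod("show", "SignalTrack", function(object) {
  cat(sprintf("SignalTrack <%s>: %d positions on %d chromosome(s)",
              object@kind, nrow(object@data),
              length(unique(object@data$chrom))))
  if (object@kind == "sirna")
    cat(sprintf(", library %.3g reads", object@libraryTotal))
  cat("\n")
})

#' @rdname signalTrack
#' @param x a `SignalTrack`.
#' @export
trackData <- function(x) {
  stopifnot(is(x, "SignalTrack"))
  x@data
}

#' @rdname signalTrack
#' @export
libraryTotal <- function(x) {
  stopifnot(is(x, "SignalTrack"))
  x@libraryTotal
}
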