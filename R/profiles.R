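# Windowed metagene profiles around genes: TE proportion, 24-nt siRNA
# TP10M, weighted methylation by context, and histone log2(treat/input),
# strand-aware, with 2 kb flanks and 40 equal gene-body bins.
#
# Geometry follows the field's conventions: 100 bp windows sliding by 10 bp
# over the 2 kb flanks give (2000-100)/10 + 1 = 191 windows per side;
# methylation uses 50 bp non-overlapping flank windows; histone signal uses
# 100 bp non-overlapping windows.  Flanks are truncated (not discarded) at
# chromosome ends, and per-window gene counts are tracked so cross-gene
# means use correct denominators.

# ---- low-level machinery ---------------------------------------------------

# per-chromosome numeric vectors from a position/value table
.trackVectors <- function(dt, valueCols, binWidth, chromLengths) {
  out <- list()
  for (ch in names(chromLengths)) {
    L <- as.integer(chromLengths[[ch]])
    sub <- dt[dt$chrom == ch, ]
    # counts/calls are anchored at the (bin) start position; window sums
    # therefore count a bin where it starts, which keeps totals additive
    vecs <- lapply(valueCols, function(vc) {
      v <- numeric(L)
      if (nrow(sub)) {
        idx <- as.integer(sub$pos)
        val <- as.numeric(sub[[vc]])
        okk <- idx >= 1L & idx <= L
        agg <- rowsum(val[okk], idx[okk])
        v[as.integer(rownames(agg))] <- agg[, 1]
      }
      v
    })
    names(vecs) <- valueCols
    out[[ch]] <- vecs
  }
  out
}

# extract [s, e] (1-based, possibly out of bounds -> NA padding)
.extractVec <- function(v, s, e, rev = FALSE) {
  n <- length(v)
  res <- rep(NA_real_, e - s + 1)
  s2 <- max(1L, s); e2 <- min(n, e)
  if (s2 <= e2) res[(s2 - s + 1):(e2 - s + 1)] <- v[s2:e2]
  if (rev) rev(res) else res
}

# sliding-window sums; windows containing NA give NA
.windowSums <- function(v, window, step) {
  n <- length(v)
  if (n < window) return(numeric(0))
  starts <- seq(1L, n - window + 1L, by = step)
  vz <- v; vz[is.na(v)] <- 0
  cs <- c(0, cumsum(vz))
  cn <- c(0, cumsum(is.na(v)))
  s <- cs[starts + window] - cs[starts]
  s[(cn[starts + window] - cn[starts]) > 0] <- NA_real_
  s
}

.flankCoords <- function(gene, flank) {
  # returns list(up = c(s, e, rev), down = c(s, e, rev)) in gene orientation
  s <- start(gene); e <- end(gene)
  if (as.character(strand(gene)) == "-") {
    list(up = c(e + 1L, e + flank, TRUE), down = c(s - flank, s - 1L, TRUE))
  } else {
    list(up = c(s - flank, s - 1L, FALSE), down = c(e + 1L, e + flank, FALSE))
  }
}

.bodyCoords <- function(gene) {
  c(start(gene), end(gene), as.character(strand(gene)) == "-")
}

# generic per-gene flank/body profile builder.
# statFun(num, den): window statistic from window sums of the numerator
# vector(s); 'den' may be NULL.
.metaProfile <- function(genes, vecs, numCol, denCol = NULL,
                         flank = 2000L, window = 100L, step = 10L,
                         bodyBins = 40L, statFun, chromLengths) {
  stopifnot(length(genes) > 0)
  nw <- (flank - window) %/% step + 1L
  upM <- matrix(NA_real_, length(genes), nw)
  dnM <- matrix(NA_real_, length(genes), nw)
  bodyM <- if (bodyBins > 0) matrix(NA_real_, length(genes), bodyBins)
           else NULL
  shortSkipped <- 0L
  for (i in seq_along(genes)) {
    g <- genes[i]
    ch <- as.character(seqnames(g))
    if (is.null(vecs[[ch]])) next
    num <- vecs[[ch]][[numCol]]
    den <- if (!is.null(denCol)) vecs[[ch]][[denCol]] else NULL
    fc <- .flankCoords(g, flank)
    for (sideTag in c("up", "down")) {
      co <- fc[[sideTag]]
      nv <- .extractVec(num, co[1], co[2], rev = as.logical(co[3]))
      dv <- if (!is.null(den))
        .extractVec(den, co[1], co[2], rev = as.logical(co[3])) else NULL
      vals <- statFun(.windowSums(nv, window, step),
                      if (is.null(dv)) NULL else .windowSums(dv, window, step))
      if (sideTag == "up") upM[i, ] <- vals else dnM[i, ] <- vals
    }
    if (!is.null(bodyM)) {
      if (width(g) < bodyBins) { shortSkipped <- shortSkipped + 1L; next }
      bc <- .bodyCoords(g)
      nv <- .extractVec(num, bc[1], bc[2], rev = as.logical(bc[3]))
      dv <- if (!is.null(den))
        .extractVec(den, bc[1], bc[2], rev = as.logical(bc[3])) else NULL
      L <- length(nv)
      binIdx <- floor((seq_len(L) - 1) * bodyBins / L) + 1L
      nb <- vapply(split(nv, binIdx), sum, numeric(1))
      db <- if (!is.null(dv)) vapply(split(dv, binIdx), sum, numeric(1))
            else NULL
      bodyM[i, ] <- statFun(nb, db)
    }
  }
  if (shortSkipped)
    warning(shortSkipped, " gene(s) shorter than ", bodyBins,
            " bp skipped for body binning")
  collect <- function(M, part, offsets) {
    data.table(part = part, win = seq_len(ncol(M)), offset = offsets,
               mean = colMeans(M, na.rm = TRUE),
               n_genes = colSums(!is.na(M)))
  }
  upOff <- -flank + (seq_len(nw) - 1L) * step  # window start rel. to TSS
  dnOff <- (seq_len(nw) - 1L) * step           # window start rel. to TTS
  out <- rbind(collect(upM, "upstream", upOff),
               if (!is.null(bodyM))
                 collect(bodyM, "body", seq_len(bodyBins)),
               collect(dnM, "downstream", dnOff))
  out[]
}

.chromLensFromGenes <- function(genes, chromLengths = NULL, pad = 5e4) {
  if (!is.null(chromLengths)) return(chromLengths)
  sl <- GenomeInfoDb::seqlengths(genes)
  if (!anyNA(sl) && length(sl)) return(sl)
  tapply(end(genes), as.character(seqnames(genes)), function(x) max(x) + pad)
}

# ---- user-facing operations ------------------------------------------------

#' Distance from genes to their nearest TE
#'
#' Minimum edge-to-edge distance from each gene to any TE on the same
#' chromosome; overlapping TEs give distance 0, and NA is returned when
#' the chromosome carries no TE.
#'
#' @param genes,tes `GRanges`.
#' @return numeric vector of distances in bp, one per gene.
#' @export
nearestTeDistance <- function(genes, tes) {
  h <- .sameSeqlevels(genes, tes)
  hits <- distanceToNearest(h[[1]], h[[2]], ignore.strand = TRUE)
  out <- rep(NA_real_, length(genes))
  out[S4Vectors::queryHits(hits)] <- mcols(hits)$distance
  out
}

#' TE proportion profile around genes
#'
#' Mean TE-covered fraction in 100 bp windows sliding by 10 bp over the
#' 2 kb upstream (anchored at the TSS) and downstream (anchored at the
#' TTS) regions, strand-aware and averaged over genes.
#'
#' @param genes `GRanges` of genes (strand used for orientation).
#' @param tes `GRanges` of TEs.
#' @param flank,window,step geometry in bp (defaults 2000/100/10, i.e. 191
#'   windows per side).
#' @param chromLengths optional named vector of chromosome lengths.
#' @return a `data.table` profile: `part` (upstream/downstream), `win`,
#'   `offset` (window start relative to TSS/TTS), `mean`, `n_genes`.
#' @export
teProportionProfile <- function(genes, tes, flank = 2000L, window = 100L,
                                step = 10L, chromLengths = NULL) {
  if (!length(genes)) stop("empty gene set")
  cl <- .chromLensFromGenes(genes, chromLengths,
                            pad = flank + 1e3)
  red <- GenomicRanges::reduce(tes, ignore.strand = TRUE)
  # expand reduced TEs into base-level indicator vectors
  vecs <- list()
  for (ch in names(cl)) {
    v <- numeric(as.integer(cl[[ch]]))
    rr <- red[as.character(seqnames(red)) == ch]
    for (j in seq_along(rr)) {
      s <- max(1L, start(rr)[j]); e <- min(length(v), end(rr)[j])
      if (s <= e) v[s:e] <- 1
    }
    vecs[[ch]] <- list(te = v)
  }
  .metaProfile(genes, vecs, "te", NULL, flank, window, step, bodyBins = 0L,
               statFun = function(num, den) num / window,
               chromLengths = cl)
}

#' 24-nt siRNA profile in TP10M
#'
#' Read counts in 100 bp windows sliding by 10 bp over the 2 kb flanks,
#' normalised to transcripts per 10 million uniquely and perfectly mapped
#' reads (TP10M = count x 1e7 / library size) and averaged over genes.
#'
#' @param track a siRNA [SignalTrack-class].
#' @param genes `GRanges` of genes.
#' @param flank,window,step geometry (defaults 2000/100/10).
#' @param chromLengths optional chromosome lengths.
#' @return profile `data.table` as in [teProportionProfile()].
#' @export
sirnaProfile <- function(track, genes, flank = 2000L, window = 100L,
                         step = 10L, chromLengths = NULL) {
  stopifnot(is(track, "SignalTrack"), track@kind == "sirna")
  if (!is.finite(track@libraryTotal) || track@libraryTotal <= 0)
    stop("siRNA track has no positive library total")
  cl <- .chromLensFromGenes(genes, chromLengths, pad = flank + 1e3)
  vecs <- .trackVectors(track@data, "count", track@binWidth, cl)
  scale <- 1e7 / track@libraryTotal
  .metaProfile(genes, vecs, "count", NULL, flank, window, step,
               bodyBins = 0L,
               statFun = function(num, den) num * scale,
               chromLengths = cl)
}

#' Weighted methylation profile by context
#'
#' Weighted methylation (sum of methylated over sum of total read calls
#' across cytosines) in 50 bp non-overlapping windows over the 2 kb
#' flanks, and in 40 equal-size bins over the gene body.  Windows without
#' covered cytosines are excluded from the cross-gene mean.
#'
#' @param track a methylation [SignalTrack-class].
#' @param genes `GRanges` of genes.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param flank,window geometry (defaults 2000/50).
#' @param bodyBins equal-size gene-body bins (default 40).
#' @param chromLengths optional chromosome lengths.
#' @return profile `data.table` with parts upstream/body/downstream.
#' @export
methylationProfile <- function(track, genes, context = c("CHH", "CG", "CHG"),
                               flank = 2000L, window = 50L, bodyBins = 40L,
                               chromLengths = NULL) {
  stopifnot(is(track, "SignalTrack"), track@kind == "methylation")
  context <- match.arg(context)
  cl <- .chromLensFromGenes(genes, chromLengths, pad = flank + 1e3)
  keep <- track@data[["context"]] == context
  dt <- track@data[keep, ]
  vecs <- .trackVectors(dt, c("methylated_reads", "total_reads"),
                        track@binWidth, cl)
  .metaProfile(genes, vecs, "methylated_reads", "total_reads",
               flank, window, step = window, bodyBins = bodyBins,
               statFun = function(num, den) {
                 out <- num / den
                 out[!is.na(den) & den == 0] <- NA_real_
                 out
               },
               chromLengths = cl)
}

#' Histone ChIP signal profile
#'
#' Per 100 bp non-overlapping window over the 2 kb flanks and per
#' gene-body bin, the signal log2((treat reads + 1) / (input reads + 1)),
#' averaged over genes.
#'
#' @param treat,input histone [SignalTrack-class] objects on the same
#'   coordinates (a single track holding both columns may be passed as
#'   `treat`, in which case `input` is ignored when NULL).
#' @param genes `GRanges` of genes.
#' @param flank,window geometry (defaults 2000/100).
#' @param bodyBins gene-body bins (default 40).
#' @param chromLengths optional chromosome lengths.
#' @return profile `data.table` with parts upstream/body/downstream.
#' @export
histoneProfile <- function(treat, input = NULL, genes, flank = 2000L,
                           window = 100L, bodyBins = 40L,
                           chromLengths = NULL) {
  stopifnot(is(treat, "SignalTrack"), treat@kind == "histone")
  dt <- treat@data
  if (!is.null(input)) {
    stopifnot(is(input, "SignalTrack"), input@kind == "histone")
    if (!setequal(unique(dt$chrom), unique(input@data$chrom)))
      stop("treat and input tracks cover different chromosomes")
    key <- c("chrom", "pos")
    dt <- merge(dt[, c("chrom", "pos", "treat_count"), with = FALSE],
                input@data[, c("chrom", "pos", "input_count"), with = FALSE],
                by = key, all = TRUE)
    dt[is.na(dt$treat_count), "treat_count"] <- 0
    dt[is.na(dt$input_count), "input_count"] <- 0
  }
  cl <- .chromLensFromGenes(genes, chromLengths, pad = flank + 1e3)
  vecs <- .trackVectors(dt, c("treat_count", "input_count"),
                        treat@binWidth, cl)
  .metaProfile(genes, vecs, "treat_count", "input_count",
               flank, window, step = window, bodyBins = bodyBins,
               statFun = function(num, den) log2((num + 1) / (den + 1)),
               chromLengths = cl)
}
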