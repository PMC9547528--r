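# Genome partitioning: windowed density/recombination tracks and automated
# segmentation of each chromosome into two arms and one pericentromeric
# region.

#' Windowed gene density and repeat length
#'
#' Statistics are measured in 1 Mb windows advancing by 500 kb along each
#' chromosome.  A gene is counted in a window if its start position lies in
#' the window (overlapping windows may therefore count a gene twice, once
#' per window, which is intended for a sliding-window density track);
#' repeat length is the repeat-covered fraction of the window (Mb/Mb).
#'
#' @param genes,repeats [GenomicRanges::GRanges] of gene and repeat (TE)
#'   annotations.  Coordinates must be positive and within the chromosome.
#' @param chromLengths named numeric vector of chromosome lengths in bp.
#' @param window,step window size and shift in bp.
#' @return a `data.table` with columns `chrom`, `window_start`,
#'   `window_end` (0-based half-open bp), `gene_density` (genes/Mb) and
#'   `repeat_length` (Mb/Mb).
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1e5, 2e6), width = 1e3))
#' windowStats(g, GenomicRanges::GRanges(), c(chr1 = 4e6))
#' @export
windowStats <- function(genes, repeats, chromLengths,
                        window = 1e6, step = 5e5) {
  stopifnot(is(genes, "GRanges"), is(repeats, "GRanges"),
            !is.null(names(chromLengths)))
  if ((length(genes) && min(start(genes)) < 1) ||
      (length(repeats) && min(start(repeats)) < 1))
    stop("negative or zero coordinates in input intervals")
  out <- vector("list", length(chromLengths))
  for (i in seq_along(chromLengths)) {
    ch <- names(chromLengths)[i]
    L <- chromLengths[[i]]
    starts <- if (L >= window) seq(0, L - window, by = step) else 0
    ends <- pmin(starts + window, L)
    g <- genes[as.character(seqnames(genes)) == ch]
    r <- repeats[as.character(seqnames(repeats)) == ch]
    gs <- start(g) - 1L  # 0-based starts
    cnt <- vapply(seq_along(starts), function(k)
      sum(gs >= starts[k] & gs < ends[k]), numeric(1))
    rep_bp <- if (length(r)) {
      cov <- GenomicRanges::coverage(GenomicRanges::reduce(r))[[ch]]
      vapply(seq_along(starts), function(k) {
        v <- IRanges::Views(cov, starts[k] + 1L, min(ends[k], length(cov)))
        if (length(v)) sum(v)[1] else 0
      }, numeric(1))
    } else rep(0, length(starts))
    out[[i]] <- data.table(
      chrom = ch, window_start = starts, window_end = ends,
      gene_density = cnt / ((ends - starts) / 1e6),
      repeat_length = rep_bp / (ends - starts))
  }
  rbindlist(out)
}

#' Piecewise recombination map from a genetic marker table
#'
#' The rate between consecutive markers is the slope \eqn{\Delta cM /
#' \Delta Mb}; a query position receives the rate of its enclosing marker
#' interval (positions outside the map get the rate of the nearest
#' terminal interval).
#'
#' @param markers a data.frame with columns `chrom`, `bp`, `cM`; within a
#'   chromosome markers must be sorted by `bp` with non-decreasing `cM`.
#' @return an object of class `recombMap`: a `data.table` of intervals
#'   (`chrom`, `start_bp`, `end_bp`, `rate`) usable with [recombRateAt()].
#' @examples
#' m <- data.frame(chrom = "chr1", bp = c(0, 2e6), cM = c(0, 4))
#' rm <- recombinationRate(m)
#' recombRateAt(rm, "chr1", 1e6)  # 2 cM/Mb
#' @export
recombinationRate <- function(markers) {
  m <- as.data.table(markers)
  stopifnot(all(c("chrom", "bp", "cM") %in% names(m)))
  out <- m[, {
    o <- order(bp)
    b <- bp[o]; c_ <- cM[o]
    if (any(diff(c_) < 0))
      stop("decreasing cM along chromosome ", .BY$chrom,
           ": inconsistent genetic map")
    if (length(b) < 2)
      stop("need >= 2 markers per chromosome for rates")
    list(start_bp = b[-length(b)], end_bp = b[-1],
         rate = diff(c_) / (diff(b) / 1e6))
  }, by = chrom]
  structure(out, class = c("recombMap", class(out)))
}

#' Look up recombination rates at positions
#'
#' @param map a `recombMap` from [recombinationRate()].
#' @param chrom character vector of chromosomes.
#' @param pos numeric vector of bp positions (recycled against `chrom`).
#' @return numeric vector of rates in cM/Mb; NA where the chromosome is not
#'   in the map.
#' @export
recombRateAt <- function(map, chrom, pos) {
  stopifnot(inherits(map, "recombMap"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  res <- rep(NA_real_, n)
  for (ch in unique(chrom)) {
    mi <- map[map$chrom == ch, ]
    sel <- which(chrom == ch)
    if (!nrow(mi)) next
    idx <- findInterval(pos[sel], mi$start_bp, rightmost.closed = FALSE)
    idx[idx < 1L] <- 1L
    idx[idx > nrow(mi)] <- nrow(mi)
    res[sel] <- mi$rate[idx]
  }
  res
}

#' Segment chromosomes into arms and a pericentromeric region
#'
#' The pericentromeric region is the maximal contiguous run of windows that
#' contains the centromere and in which the smoothed recombination rate is
#' below `rMax` and the repeat fraction exceeds `tMin`; the flanking
#' windows form the two arms.  Explicit boundaries can be supplied instead
#' to reproduce externally (e.g. manually) defined partitions.
#'
#' @param track a windowed density track from [windowStats()].  If it lacks
#'   a `recombination` column, one is added from `recmap`.
#' @param centromere `GRanges` of presumed centromere positions, one per
#'   chromosome.
#' @param recmap optional `recombMap` used to annotate the track.
#' @param rMax recombination threshold in cM/Mb (default 1).
#' @param tMin repeat-length threshold; default is the per-chromosome
#'   median repeat fraction.
#' @param smooth width (in windows) of the running-mean smoother applied to
#'   the recombination signal before thresholding.
#' @param boundaries optional data.frame with columns `chrom`,
#'   `peri_start`, `peri_end` (bp, 0-based half-open) overriding the
#'   threshold rule.
#' @param chromLengths named numeric vector of chromosome lengths.
#' @return a [GenomePartition-class].
#' @export
segmentGenome <- function(track, centromere, chromLengths, recmap = NULL,
                          rMax = 1, tMin = NULL, smooth = 5L,
                          boundaries = NULL) {
  tr <- as.data.table(track)
  if (!is.null(recmap) && !"recombination" %in% names(tr)) {
    mid <- (tr$window_start + tr$window_end) / 2
    tr[, recombination := recombRateAt(recmap, tr$chrom, mid)]
  }
  parts <- list(); cens <- list()
  for (ch in names(chromLengths)) {
    L <- chromLengths[[ch]]
    cen <- centromere[as.character(seqnames(centromere)) == ch]
    if (!length(cen))
      stop("no centromere given for chromosome ", ch)
    if (start(cen) < 1 || end(cen) > L)
      stop("centromere outside chromosome ", ch)
    if (!is.null(boundaries)) {
      b <- boundaries[boundaries$chrom == ch, ]
      if (!nrow(b)) stop("no boundaries for chromosome ", ch)
      ps <- b$peri_start[1]; pe <- b$peri_end[1]
    } else {
      ti <- tr[chrom == ch][order(window_start)]
      if (!nrow(ti)) stop("track does not cover chromosome ", ch)
      if (!"recombination" %in% names(ti))
        stop("track lacks recombination; supply 'recmap'")
      r <- .runmean(ti$recombination, smooth)
      thr <- if (is.null(tMin)) stats::median(ti$repeat_length) else tMin
      ok <- r < rMax & ti$repeat_length > thr
      cenw <- which(ti$window_start < end(cen) & ti$window_end > start(cen))
      if (!length(cenw)) stop("centromere not covered by track on ", ch)
      run <- .maxRunContaining(ok, cenw)
      if (is.null(run)) {
        # no qualifying window at the centromere: fall back to the
        # centromere-overlapping windows themselves
        warning("no window at the centromere of ", ch,
                " passes the thresholds; peri set to the centromeric windows")
        run <- range(cenw)
      }
      ps <- ti$window_start[run[1]]
      pe <- ti$window_end[run[2]]
      if (run[1] == 1L && run[2] == nrow(ti)) {
        warning("thresholds admit every window on ", ch,
                ": peri spans the whole chromosome, arms are empty")
        ps <- 0; pe <- L
      }
    }
    ps <- max(0, ps); pe <- min(L, pe)
    # clamp so the centromere stays inside
    ps <- min(ps, start(cen) - 1L); pe <- max(pe, end(cen))
    rows <- list()
    if (ps > 0) rows$arm1 <- c(1, ps)
    rows$peri <- c(ps + 1, pe)
    if (pe < L) rows$arm2 <- c(pe + 1, L)
    parts[[ch]] <- data.table(
      chrom = ch,
      start = vapply(rows, `[`, numeric(1), 1),
      end = vapply(rows, `[`, numeric(1), 2),
      region = names(rows))
    cens[[ch]] <- data.table(chrom = ch, start = start(cen)[1],
                             end = end(cen)[1])
  }
  pdt <- rbindlist(parts)
  cdt <- rbindlist(cens)
  new("GenomePartition",
      partition = GRanges(pdt$chrom, IRanges(pdt$start, pdt$end),
                          region = pdt$region),
      centromere = GRanges(cdt$chrom, IRanges(cdt$start, cdt$end)),
      track = tr)
}

.runmean <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k == 1L || length(x) < 2) return(x)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - k %/% 2L); hi <- min(n, i + k %/% 2L)
    mean(x[lo:hi], na.rm = TRUE)
  }, numeric(1))
}

# maximal contiguous TRUE run whose index range intersects 'anchor'
.maxRunContaining <- function(ok, anchor) {
  if (!any(ok[anchor])) return(NULL)
  a <- anchor[ok[anchor]][1]
  lo <- a; while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- a; while (hi < length(ok) && ok[hi + 1L]) hi <- hi + 1L
  c(lo, hi)
}

#' Classify features as arm or pericentromeric
#'
#' A feature is labelled by the partition interval containing its midpoint,
#' giving every gene or ACR a single unambiguous chromatin-environment
#' label.
#'
#' @param x a `GRanges` of features.
#' @param partition a [GenomePartition-class].
#' @return character vector, `"arm"` or `"peri"`, one per feature.
#' @export
classifyRegion <- function(x, partition) {
  stopifnot(is(partition, "GenomePartition"))
  p <- partition@partition
  miss <- setdiff(unique(as.character(seqnames(x))),
                  unique(as.character(seqnames(p))))
  if (length(miss))
    stop("chromosome(s) absent from partition: ", paste(miss, collapse = ", "))
  mids <- GRanges(seqnames(x),
                  IRanges(floor((start(x) + end(x)) / 2), width = 1L))
  h <- .sameSeqlevels(mids, p)
  hit <- findOverlaps(h[[1]], h[[2]], select = "first")
  if (anyNA(hit)) stop("feature midpoint outside the partition")
  reg <- mcols(p)$region[hit]
  ifelse(reg == "peri", "peri", "arm")
}

#' Export a partition as BED
#'
#' Writes the arm1/peri/arm2 intervals as a BED file (name column =
#' region label).
#'
#' @param partition a [GenomePartition-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writePartitionBed <- function(partition, file) {
  p <- partition@partition
  gr <- granges(p)
  names(gr) <- mcols(p)$region
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}
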