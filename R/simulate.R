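# Synthetic two-subgenome dataset generator.  Emulates the contrasts a
# paleotetraploid genome shows between its dominant (maize1-like) and
# recessive (maize2-like) subgenomes and between chromosomal arms and
# pericentromeric regions: arm/peri gene- and TE-density contrasts,
# region- and subgenome-dependent gene loss and substitution rates,
# two-fold-scale expression dominance, flanking siRNA/CHH methylation
# islands, and biased ACR retention.  Every downstream stage of the
# package can be exercised, and every planted bias recovered, from the
# files it writes.

#' Construct a simulation configuration
#'
#' Returns a validated [SimConfig-class].  The defaults describe the
#' study conditions the package's acceptance checks run under: three
#' chromosomes of 15 Mb per subgenome with a 40% pericentromere, arm/peri
#' gene densities 75/25 per Mb (roughly 2,500 ancestral genes and 600-700
#' retained homoeolog pairs) and TE fractions 0.2/0.6, mutually
#' exclusive copy-loss probabilities derived from the singleton:WGD ratios
#' the package is designed to reproduce (deletion probability of the copy
#' in an arm 0.19 for maize1 / 0.50 for maize2, in a pericentromere 0.24 /
#' 0.55), synonymous rates around 0.12-0.16 with lower values
#' in pericentromeres, nonsynonymous rates elevated in maize2, a two-fold
#' expression dominance effect in 40% of arm-located maize1 pairs, CHH
#' islands of height 0.6 at +/-500 bp of gene boundaries (maize2 scaled
#' by 1.3), and ACR retention biased toward maize1 and arms.
#'
#' @param seed integer RNG seed.
#' @param ... overrides for any [SimConfig-class] slot (slot names).
#' @return a `SimConfig`.
#' @examples
#' cfg <- simConfig(seed = 1, nChromosomes = 1L, chromLength = 2e6)
#' @export
simConfig <- function(seed = 1L, ...) {
  defaults <- list(
    seed = as.integer(seed),
    nChromosomes = 3L,
    chromLength = 15e6,
    periFraction = 0.4,
    geneDensityArm = 75,
    geneDensityPeri = 25,
    teDensityArm = 0.2,
    teDensityPeri = 0.6,
    lossProb = c(m1_arm = 0.19, m1_peri = 0.24,
                 m2_arm = 0.50, m2_peri = 0.55),
    synRate = c(m1_arm = 0.150, m1_peri = 0.120,
                m2_arm = 0.160, m2_peri = 0.125),
    nonsynRate = c(m1_arm = 0.040, m1_peri = 0.048,
                   m2_arm = 0.055, m2_peri = 0.050),
    dominanceEffect = 2.0,
    dominanceFraction = 0.4,
    exprNoiseSd = 0.3,
    chhIslandHeight = 0.6,
    m2IslandFactor = 1.3,
    islandOffset = 500,
    acrRetentionProb = c(m1_arm = 0.80, m1_peri = 0.55,
                         m2_arm = 0.60, m2_peri = 0.45),
    nTissues = 24L,
    nBlocksPerChrom = 6L,
    cdsCodons = 300L,
    tandemProb = 0.05,
    nPanel = 20L
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(defaults))
  if (length(bad))
    stop("unknown SimConfig field(s): ", paste(bad, collapse = ", "))
  defaults[names(ov)] <- ov
  for (nm in c("seed", "nChromosomes", "nTissues", "nBlocksPerChrom",
               "cdsCodons", "nPanel"))
    defaults[[nm]] <- as.integer(defaults[[nm]])
  do.call(new, c(list("SimConfig"), defaults))
}

.rateKey <- function(sub, region) paste0(sub, "_", region)

# geometry: chromosome names/lengths, per-chromosome peri intervals
# (maize2 pericentromeres are shifted to mimic post-WGD rearrangement, so
# the four chromatin-environment categories all arise), centromeres
.simGeometry <- function(config) {
  n <- config@nChromosomes
  L <- config@chromLength
  p <- config@periFraction
  chroms <- c(paste0("m1_chr", seq_len(n)), paste0("m2_chr", seq_len(n)))
  lens <- setNames(rep(L, 2 * n), chroms)
  peri <- rbindlist(lapply(seq_len(2 * n), function(i) {
    sub <- if (i <= n) "m1" else "m2"
    k <- if (i <= n) i else i - n
    center <- if (sub == "m1") L / 2 else
      L / 2 + 0.12 * L * ((-1)^k)
    data.table(chrom = chroms[i], sub = sub,
               peri_start = round(center - p * L / 2),
               peri_end = round(center + p * L / 2))
  }))
  cenHalf <- round(p * L * 0.02)
  cen <- GRanges(peri$chrom,
                 IRanges(round((peri$peri_start + peri$peri_end) / 2) -
                           cenHalf,
                         round((peri$peri_start + peri$peri_end) / 2) +
                           cenHalf))
  list(chromLengths = lens, peri = peri, centromere = cen, n = n, L = L)
}

.regionOf <- function(pos, periStart, periEnd) {
  ifelse(pos > periStart & pos <= periEnd, "peri", "arm")
}

# sample 'count' sorted positions in [lo, hi) with piecewise-constant
# density given by the peri interval of the chromosome
.samplePos <- function(count, lo, hi, periStart, periEnd, dArm, dPeri,
                       minGap = 1200) {
  if (count == 0) return(numeric(0))
  binW <- 1e5
  starts <- seq(lo, hi - 1, by = binW)
  ends <- pmin(starts + binW, hi)
  mids <- (starts + ends) / 2
  w <- ifelse(.regionOf(mids, periStart, periEnd) == "peri", dPeri, dArm) *
    (ends - starts)
  if (sum(w) <= 0) w <- rep(1, length(w))
  bins <- sample.int(length(starts), count, replace = TRUE, prob = w)
  pos <- sort(starts[bins] + runif(count) * (ends[bins] - starts[bins]))
  # enforce spacing so gene models never overlap
  for (i in seq_len(count)[-1])
    if (pos[i] - pos[i - 1] < minGap) pos[i] <- pos[i - 1] + minGap
  round(pmin(pos, hi - minGap))
}

# ancestral gene layout: positions of both copies, blocks, regions
.simGenes <- function(config, geom) {
  n <- geom$n; L <- geom$L
  periOf <- function(ch) geom$peri[geom$peri$chrom == ch, ]
  allGenes <- list()
  blockTab <- list()
  gid <- 0L
  # maize1 layout + block plan
  m2Plan <- list()
  for (k in seq_len(n)) {
    ch1 <- paste0("m1_chr", k)
    p1 <- periOf(ch1)
    armMb <- (L - (p1$peri_end - p1$peri_start)) / 1e6
    periMb <- (p1$peri_end - p1$peri_start) / 1e6
    Nk <- round(config@geneDensityArm * armMb +
                  config@geneDensityPeri * periMb)
    pos1 <- .samplePos(Nk, 1, L, p1$peri_start, p1$peri_end,
                       config@geneDensityArm, config@geneDensityPeri)
    nB <- config@nBlocksPerChrom
    blk <- as.integer(cut(seq_len(Nk), breaks = nB, labels = FALSE))
    ids <- gid + seq_len(Nk)
    gid <- gid + Nk
    allGenes[[k]] <- data.table(
      anc_id = ids, anc_chrom = k, anc_idx = seq_len(Nk),
      m1_chrom = ch1, m1_pos = pos1, block_local = blk)
    for (b in seq_len(nB)) {
      j <- ((k - 1L) + (b - 1L)) %% n + 1L
      m2Plan[[length(m2Plan) + 1L]] <- data.table(
        anc_chrom = k, block_local = b, m2_chrom_idx = j,
        n_genes = sum(blk == b))
    }
  }
  genes <- rbindlist(allGenes)
  plan <- rbindlist(m2Plan)
  # maize2 layout: each m2 chromosome hosts its incoming blocks at the
  # same relative bp span as the block occupies on its m1 chromosome
  # (synteny preserves large-scale position), so the partner-region
  # correlation between subgenomes mirrors a real paleotetraploid; gene
  # positions within the span follow the m2 chromosome's own arm/peri
  # density profile
  genes[, m2_chrom := NA_character_]
  genes[, m2_pos := NA_real_]
  for (j in seq_len(n)) {
    ch2 <- paste0("m2_chr", j)
    p2 <- periOf(ch2)
    inc <- plan[plan$m2_chrom_idx == j, ][order(block_local, anc_chrom)]
    if (!nrow(inc)) next
    prevEnd <- 1e4
    for (bi in seq_len(nrow(inc))) {
      sel <- genes$anc_chrom == inc$anc_chrom[bi] &
        genes$block_local == inc$block_local[bi]
      cnt <- sum(sel)
      relLo <- min(genes$m1_pos[sel]) / L
      relHi <- max(genes$m1_pos[sel]) / L
      lo <- max(prevEnd, round(relLo * (L - 2e4)))
      hi <- max(lo + cnt * 1500, round(relHi * (L - 2e4)))
      prevEnd <- hi + 1
      pos2 <- .samplePos(cnt, lo, hi,
                         p2$peri_start, p2$peri_end,
                         config@geneDensityArm, config@geneDensityPeri)
      genes$m2_chrom[sel] <- ch2
      genes$m2_pos[sel] <- pos2
    }
  }
  span <- config@cdsCodons * 3L
  for (sideTag in c("m1", "m2")) {
    pcol <- paste0(sideTag, "_pos"); ccol <- paste0(sideTag, "_chrom")
    ps <- geom$peri[match(genes[[ccol]], geom$peri$chrom), ]
    genes[, paste0(sideTag, "_region") := .regionOf(
      genes[[pcol]] + span / 2, ps$peri_start, ps$peri_end)]
  }
  genes[, strand := sample(c("+", "-"), .N, replace = TRUE)]
  genes[, sorghum_gene := sprintf("sb%02dg%05d", anc_chrom, anc_idx)]
  genes[, m1_gene := sprintf("m1g%02d_%05d", anc_chrom, anc_idx)]
  genes[, m2_gene := sprintf("m2g%02d_%05d", anc_chrom, anc_idx)]
  genes[]
}

# mutually exclusive copy loss per ancestral gene
.simLoss <- function(genes, config) {
  p1 <- config@lossProb[.rateKey("m1", genes$m1_region)]
  p2 <- config@lossProb[.rateKey("m2", genes$m2_region)]
  u <- runif(nrow(genes))
  status <- fifelse(u < p1, "singleton_m2",
            fifelse(u < p1 + p2, "singleton_m1", "pair"))
  status
}

# codon machinery for sequence evolution (shares the cache with ng86)
.codonAlternativesTable <- function() {
  .codonTable()
  if (!is.null(.ngCache$synAlt)) return(invisible(NULL))
  gc <- .ngCache$aa
  codons <- names(gc)[gc != "*"]
  synAlt <- list(); nonAlt <- list()
  for (cd in codons) {
    sa <- character(); na <- character()
    for (p in 1:3) for (nt in c("A", "C", "G", "T")) {
      if (substr(cd, p, p) == nt) next
      alt <- cd; substr(alt, p, p) <- nt
      if (gc[[alt]] == "*") next  # never create in-frame stops
      if (gc[[alt]] == gc[[cd]]) sa <- c(sa, alt) else na <- c(na, alt)
    }
    synAlt[[cd]] <- sa; nonAlt[[cd]] <- na
  }
  .ngCache$synAlt <- synAlt
  .ngCache$nonAlt <- nonAlt
  .ngCache$sense <- codons
  .ngCache$synAltN <- vapply(synAlt, length, integer(1))
  .ngCache$nonAltN <- vapply(nonAlt, length, integer(1))
  invisible(NULL)
}

.randomCds <- function(nCodons) {
  .codonAlternativesTable()
  sample(.ngCache$sense, nCodons, replace = TRUE)
}

# evolve a codon vector: Poisson numbers of synonymous and nonsynonymous
# single-nucleotide substitutions at the configured per-site rates, sites
# chosen proportionally to their mutational opportunity, in-frame stops
# never created
.evolveCds <- function(codons, synRate, nonsynRate) {
  .codonAlternativesTable()
  S <- sum(.ngCache$syn[codons])
  N <- 3 * length(codons) - S
  nS <- stats::rpois(1, synRate * S)
  nN <- stats::rpois(1, nonsynRate * N)
  for (kind in c("syn", "non")) {
    cnt <- if (kind == "syn") nS else nN
    altList <- if (kind == "syn") .ngCache$synAlt else .ngCache$nonAlt
    altN <- if (kind == "syn") .ngCache$synAltN else .ngCache$nonAltN
    for (z in seq_len(cnt)) {
      w <- altN[codons]
      if (sum(w) == 0) break
      i <- sample.int(length(codons), 1L, prob = w)
      opts <- altList[[codons[i]]]
      codons[i] <- opts[sample.int(length(opts), 1L)]
    }
  }
  codons
}

#' Generate a signal track for a set of genes
#'
#' Standalone access to the generator's track models.  siRNA tracks get
#' Gaussian-shaped read-count islands centred `islandOffset` bp outside
#' the TSS and TTS; methylation tracks carry per-cytosine
#' methylated/total read calls with CHH islands at the same offsets over
#' a 0.05 background (CG/CHG are flat); histone tracks carry 100 bp
#' binned treat/input counts with treat enrichment over gene bodies.
#'
#' @param kind `"sirna"`, `"methylation"` or `"histone"`.
#' @param genes `GRanges` of genes; optional metadata columns `subgenome`
#'   (`"m1"`/`"m2"`) and `region` (`"arm"`/`"peri"`) modulate island
#'   heights and enrichment (defaults `"m1"`, `"arm"`).
#' @param config a [SimConfig-class].
#' @return a [SignalTrack-class].
#' @export
generateTrack <- function(kind = c("sirna", "methylation", "histone"),
                          genes, config) {
  kind <- match.arg(kind)
  if (!length(genes)) stop("'genes' must be non-empty")
  sub <- mcols(genes)$subgenome
  if (is.null(sub)) sub <- rep("m1", length(genes))
  off <- config@islandOffset
  sigma <- 100
  gs <- start(genes); ge <- end(genes)
  ch <- as.character(seqnames(genes))
  if (kind == "sirna") {
    grid <- 10L
    rows <- lapply(seq_along(genes), function(i) {
      centers <- c(gs[i] - off, ge[i] + off)
      h <- 4 * if (sub[i] == "m2") config@m2IslandFactor else 1
      pos <- unlist(lapply(centers, function(cc)
        seq(cc - 300, cc + 300, by = grid)))
      d <- unlist(lapply(centers, function(cc)
        abs(seq(cc - 300, cc + 300, by = grid) - cc)))
      lam <- h * exp(-d^2 / (2 * sigma^2))
      data.table(chrom = ch[i], pos = as.integer(pos),
                 count = stats::rpois(length(pos), lam))
    })
    dt <- rbindlist(rows)[pos >= 1][count > 0]
    dt <- dt[, .(count = sum(count)), by = .(chrom, pos)]
    lib <- sum(dt$count) + 5e6
    signalTrack("sirna", dt[order(chrom, pos)], libraryTotal = lib,
                binWidth = grid)
  } else if (kind == "methylation") {
    rows <- lapply(seq_along(genes), function(i) {
      h <- config@chhIslandHeight *
        if (sub[i] == "m2") config@m2IslandFactor else 1
      h <- min(h, 0.95)
      pos <- seq(gs[i] - 2000, ge[i] + 2000, by = 20L)
      d <- pmin(abs(pos - (gs[i] - off)), abs(pos - (ge[i] + off)))
      level <- 0.05 + h * exp(-d^2 / (2 * sigma^2))
      tot <- 1L + stats::rpois(length(pos), 7)
      chh <- data.table(chrom = ch[i], pos = as.integer(pos),
                        context = "CHH",
                        methylated_reads = stats::rbinom(length(pos), tot,
                                                         pmin(level, 1)),
                        total_reads = tot)
      cgp <- seq(gs[i] - 2000, ge[i] + 2000, by = 60L)
      tot2 <- 1L + stats::rpois(length(cgp), 7)
      cg <- data.table(chrom = ch[i], pos = as.integer(cgp), context = "CG",
                       methylated_reads = stats::rbinom(length(cgp), tot2,
                                                        0.7),
                       total_reads = tot2)
      rbind(chh, cg)
    })
    dt <- rbindlist(rows)[pos >= 1]
    dt <- unique(dt, by = c("chrom", "pos", "context"))
    signalTrack("methylation", dt[order(chrom, pos)], binWidth = 1L)
  } else {
    reg <- mcols(genes)$region
    if (is.null(reg)) reg <- rep("arm", length(genes))
    rows <- lapply(seq_along(genes), function(i) {
      pos <- seq(gs[i] - 2000, ge[i] + 2000, by = 100L)
      enrich <- 1.2 + if (sub[i] == "m1" && reg[i] == "arm") 0.6 else 0
      data.table(chrom = ch[i], pos = as.integer(pos),
                 treat_count = stats::rpois(length(pos), 10 * enrich),
                 input_count = stats::rpois(length(pos), 10))
    })
    dt <- rbindlist(rows)[pos >= 1]
    dt <- unique(dt, by = c("chrom", "pos"))
    signalTrack("histone", dt[order(chrom, pos)], binWidth = 100L)
  }
}

#' Generate the complete synthetic dataset
#'
#' Writes every input the analysis pipeline consumes: gene annotation
#' (GFF3), TE annotation (BED, class in the name column), genetic marker
#' map, syntelog table, ancestral ("sorghum-like") and evolved maize CDS
#' FASTA (gap-free and equal-length per syntelog, i.e. already aligned),
#' FPKM and protein matrices, SNP + GERP table with a genotype panel,
#' siRNA/methylation/histone signal tracks, ACR BED with accessibility
#' scores, ACR homology table, chromatin loops (BEDPE), chromosome sizes,
#' and a ground-truth JSON used by parameter-recovery tests.  The same
#' config and seed give byte-identical output files.
#'
#' @param config a [SimConfig-class].
#' @param outDir output directory (created if needed).
#' @return invisibly, a `data.table` manifest (`file`, `records`), also
#'   written to `manifest.tsv`.
#' @export
generateDataset <- function(config, outDir) {
  validObject(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config@seed)
  geom <- .simGeometry(config)
  genes <- .simGenes(config, geom)
  genes[, status := .simLoss(genes, config)]
  genes[, tandem := runif(.N) < config@tandemProb]
  span <- config@cdsCodons * 3L
  manifest <- list()
  addFile <- function(name, records)
    manifest[[length(manifest) + 1L]] <<- data.table(file = name,
                                                     records = records)
  # --- chromosome sizes
  fwrite(data.table(chrom = names(geom$chromLengths),
                    length = as.integer(geom$chromLengths)),
         file.path(outDir, "chrom.sizes"), sep = "\t", col.names = FALSE)
  addFile("chrom.sizes", length(geom$chromLengths))
  # --- gene annotation (retained copies only)
  keep1 <- genes$status %in% c("pair", "singleton_m1")
  keep2 <- genes$status %in% c("pair", "singleton_m2")
  allGr <- GRanges(
    c(genes$m1_chrom[keep1], genes$m2_chrom[keep2]),
    IRanges(c(genes$m1_pos[keep1], genes$m2_pos[keep2]), width = span),
    strand = c(genes$strand[keep1], genes$strand[keep2]),
    seqlengths = geom$chromLengths)
  names(allGr) <- c(genes$m1_gene[keep1], genes$m2_gene[keep2])
  mcols(allGr)$type <- "gene"
  mcols(allGr)$ID <- names(allGr)
  rtracklayer::export(allGr, file.path(outDir, "genes.gff3"),
                      format = "GFF3")
  addFile("genes.gff3", length(allGr))
  # --- syntelog table (lost copies are NA but the row remains)
  syn <- data.table(
    m1_gene = ifelse(keep1, genes$m1_gene, NA_character_),
    m2_gene = ifelse(keep2, genes$m2_gene, NA_character_),
    sorghum_gene = genes$sorghum_gene,
    tandem = genes$tandem)
  fwrite(syn, file.path(outDir, "syntelogs.tsv"), sep = "\t")
  addFile("syntelogs.tsv", nrow(syn))
  # --- marker map
  markers <- rbindlist(lapply(names(geom$chromLengths), function(ch) {
    p <- geom$peri[geom$peri$chrom == ch, ]
    bp <- seq(0, geom$L, by = 5e5)
    mid <- bp + 2.5e5
    slope <- ifelse(.regionOf(mid, p$peri_start, p$peri_end) == "peri",
                    0.2, 2.5) + runif(length(bp), 0, 0.05)
    data.table(chrom = ch, bp = bp,
               cM = cumsum(c(0, slope[-length(slope)] * 0.5)))
  }))
  fwrite(markers, file.path(outDir, "markers.tsv"), sep = "\t")
  addFile("markers.tsv", nrow(markers))
  # --- TEs: background per region + extra elements planted near maize2
  # (and fewer near maize1) gene flanks
  teRows <- list()
  for (ch in names(geom$chromLengths)) {
    p <- geom$peri[geom$peri$chrom == ch, ]
    for (reg in c("arm1", "peri", "arm2")) {
      iv <- switch(reg,
        arm1 = c(1, p$peri_start),
        peri = c(p$peri_start + 1, p$peri_end),
        arm2 = c(p$peri_end + 1, geom$L))
      dens <- if (reg == "peri") config@teDensityPeri else
        config@teDensityArm
      target <- dens * (iv[2] - iv[1])
      if (target <= 0) next
      lens <- numeric(0)
      while (sum(lens) < target)
        lens <- c(lens, 500 + stats::rexp(50, 1 / 2500))
      lens <- round(lens[cumsum(lens) <= target + 3000])
      st <- round(runif(length(lens), iv[1], iv[2] - lens))
      teRows[[length(teRows) + 1L]] <- data.table(
        chrom = ch, start = st, end = st + lens,
        class = sample(c("LTR", "DNA"), length(lens), TRUE, c(.75, .25)))
    }
  }
  flankTe <- function(sel, ccol, pcol, prob) {
    idx <- which(sel & runif(nrow(genes)) < prob)
    if (!length(idx)) return(NULL)
    d <- round(runif(length(idx), 50, 800))
    data.table(chrom = genes[[ccol]][idx],
               start = genes[[pcol]][idx] - d - 500,
               end = genes[[pcol]][idx] - d,
               class = "LTR")
  }
  teRows[[length(teRows) + 1L]] <- flankTe(keep1, "m1_chrom", "m1_pos", .15)
  teRows[[length(teRows) + 1L]] <- flankTe(keep2, "m2_chrom", "m2_pos", .35)
  tes <- rbindlist(teRows)[start >= 1]
  teGr <- GRanges(tes$chrom, IRanges(tes$start, tes$end))
  names(teGr) <- tes$class
  rtracklayer::export(teGr, file.path(outDir, "tes.bed"), format = "BED")
  addFile("tes.bed", length(teGr))
  # --- sequences: ancestral + evolved copies
  .codonAlternativesTable()
  anc <- lapply(seq_len(nrow(genes)), function(i)
    .randomCds(config@cdsCodons))
  seqs1 <- character(nrow(genes)); seqs2 <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    if (keep1[i])
      seqs1[i] <- paste(.evolveCds(
        anc[[i]],
        config@synRate[[.rateKey("m1", genes$m1_region[i])]],
        config@nonsynRate[[.rateKey("m1", genes$m1_region[i])]]),
        collapse = "")
    if (keep2[i])
      seqs2[i] <- paste(.evolveCds(
        anc[[i]],
        config@synRate[[.rateKey("m2", genes$m2_region[i])]],
        config@nonsynRate[[.rateKey("m2", genes$m2_region[i])]]),
        collapse = "")
  }
  ancChar <- vapply(anc, paste, character(1), collapse = "")
  sorghum <- Biostrings::DNAStringSet(setNames(ancChar, genes$sorghum_gene))
  Biostrings::writeXStringSet(sorghum, file.path(outDir, "sorghum_cds.fa"))
  addFile("sorghum_cds.fa", length(sorghum))
  maize <- Biostrings::DNAStringSet(c(
    setNames(seqs1[keep1], genes$m1_gene[keep1]),
    setNames(seqs2[keep2], genes$m2_gene[keep2])))
  Biostrings::writeXStringSet(maize, file.path(outDir, "maize_cds.fa"))
  addFile("maize_cds.fa", length(maize))
  # --- expression + protein matrices
  isPair <- genes$status == "pair"
  nPairs <- sum(isPair)
  eligible <- which(isPair & genes$m1_region == "arm")
  nAff <- round(config@dominanceFraction * length(eligible))
  affected <- sort(sample(eligible, nAff))
  affFlag <- seq_len(nrow(genes)) %in% affected
  base <- stats::rnorm(nrow(genes), log(8), 1)
  base[!isPair] <- base[!isPair] - 0.5  # singletons expressed lower
  tissues <- paste0("tissue_", seq_len(config@nTissues))
  tissEff <- matrix(stats::rnorm(nrow(genes) * config@nTissues, 0, 0.4),
                    nrow(genes))
  mk <- function(idx, dom, noiseSd) {
    noise <- matrix(stats::rnorm(length(idx) * config@nTissues, 0, noiseSd),
                    length(idx))
    exp(base[idx] + tissEff[idx, , drop = FALSE] + noise +
          log(dom))
  }
  fm1 <- mk(which(keep1), ifelse(affFlag[keep1], config@dominanceEffect, 1),
            config@exprNoiseSd)
  fm2 <- mk(which(keep2), 1, config@exprNoiseSd)
  fpkm <- rbind(
    data.table(gene = genes$m1_gene[keep1], as.data.table(fm1)),
    data.table(gene = genes$m2_gene[keep2], as.data.table(fm2)))
  setnames(fpkm, c("gene", tissues))
  fwrite(fpkm, file.path(outDir, "fpkm.tsv"), sep = "\t")
  addFile("fpkm.tsv", nrow(fpkm))
  pm1 <- mk(which(keep1),
            ifelse(affFlag[keep1], sqrt(config@dominanceEffect), 1),
            config@exprNoiseSd + 0.2)
  pm2 <- mk(which(keep2), 1, config@exprNoiseSd + 0.2)
  prot <- rbind(
    data.table(gene = genes$m1_gene[keep1], as.data.table(pm1)),
    data.table(gene = genes$m2_gene[keep2], as.data.table(pm2)))
  setnames(prot, c("gene", paste0("sample_", seq_len(config@nTissues))))
  fwrite(prot, file.path(outDir, "protein.tsv"), sep = "\t")
  addFile("protein.tsv", nrow(prot))
  # --- SNPs with GERP scores + genotype panel (pair genes only, as the
  # genetic-load comparison is between homoeologs)
  snpRows <- list(); panelRows <- list()
  snpCounter <- 0L
  for (i in which(isPair)) for (sideTag in c("m1", "m2")) {
    gid <- genes[[paste0(sideTag, "_gene")]][i]
    reg <- genes[[paste0(sideTag, "_region")]][i]
    nsnp <- stats::rpois(1, 4)
    if (!nsnp) next
    ids <- paste0("snp", snpCounter + seq_len(nsnp))
    snpCounter <- snpCounter + nsnp
    cls <- sample(c("syn", "nonsyn"), nsnp, TRUE)
    gerp <- stats::rnorm(nsnp, 0.4, 1)
    freq <- stats::rbeta(nsnp, 0.6, 3)
    deleterious <- cls == "nonsyn" & gerp > 0
    # recessive subgenome carries more derived deleterious alleles
    freq[deleterious & sideTag == "m2"] <-
      pmin(freq[deleterious & sideTag == "m2"] * 1.6, 0.95)
    off <- sort(sample.int(span, nsnp))
    snpRows[[length(snpRows) + 1L]] <- data.table(
      chrom = genes[[paste0(sideTag, "_chrom")]][i],
      pos = genes[[paste0(sideTag, "_pos")]][i] + off,
      snp_id = ids, gene = gid, ref = "A", alt = "G", ancestral = "A",
      class = cls, gerp = round(gerp, 3))
    panelRows[[length(panelRows) + 1L]] <- data.table(
      snp_id = ids,
      matrix(stats::rbinom(nsnp * config@nPanel, 2, rep(freq,
                                                        config@nPanel)),
             nsnp, config@nPanel,
             dimnames = list(NULL, paste0("ind", seq_len(config@nPanel)))))
  }
  snps <- rbindlist(snpRows)
  panel <- rbindlist(panelRows)
  fwrite(snps, file.path(outDir, "snps.tsv"), sep = "\t")
  addFile("snps.tsv", nrow(snps))
  fwrite(panel, file.path(outDir, "panel.tsv"), sep = "\t")
  addFile("panel.tsv", nrow(panel))
  # --- signal tracks
  trackGenes <- allGr
  mcols(trackGenes)$subgenome <- substr(names(allGr), 1, 2)
  mcols(trackGenes)$region <- c(genes$m1_region[keep1],
                                genes$m2_region[keep2])
  sir <- generateTrack("sirna", trackGenes, config)
  sirLines <- c(sprintf("# library_total=%.0f", sir@libraryTotal),
                paste(names(sir@data), collapse = "\t"),
                sir@data[, paste(chrom, pos, count, sep = "\t")])
  writeLines(sirLines, file.path(outDir, "sirna.tsv"))
  addFile("sirna.tsv", nrow(sir@data))
  met <- generateTrack("methylation", trackGenes, config)
  fwrite(met@data, file.path(outDir, "methylation.tsv"), sep = "\t")
  addFile("methylation.tsv", nrow(met@data))
  his <- generateTrack("histone", trackGenes, config)
  fwrite(his@data, file.path(outDir, "histone.tsv"), sep = "\t")
  addFile("histone.tsv", nrow(his@data))
  # --- ACRs + homology + loops
  acrRows <- list(); homRows <- list()
  ancHasAcr <- runif(nrow(genes)) < 0.9
  sorAcr <- ifelse(runif(nrow(genes)) < 0.65,
                   paste0("sACR_", genes$sorghum_gene), NA_character_)
  acrType <- sample(c("genic", "proximal", "distal"), nrow(genes), TRUE,
                    c(0.45, 0.35, 0.20))
  typeOffset <- function(tp, n) {
    # offset of the ACR start upstream of the TSS
    ifelse(tp == "genic", -round(runif(n, 0, 150)),
    ifelse(tp == "proximal", round(runif(n, 300, 1900)),
           round(runif(n, 2400, 8000))))
  }
  offs <- typeOffset(acrType, nrow(genes))
  retained <- list(
    m1 = keep1 & ancHasAcr &
      runif(nrow(genes)) <
        config@acrRetentionProb[.rateKey("m1", genes$m1_region)],
    m2 = keep2 & ancHasAcr &
      runif(nrow(genes)) <
        config@acrRetentionProb[.rateKey("m2", genes$m2_region)])
  for (sideTag in c("m1", "m2")) {
    sel <- which(retained[[sideTag]])
    if (!length(sel)) next
    tss <- genes[[paste0(sideTag, "_pos")]][sel]
    st <- pmax(1, tss - offs[sel] - 300)  # 1-based start, width 300
    reg <- genes[[paste0(sideTag, "_region")]][sel]
    score <- stats::rnorm(length(sel),
                          5 + ifelse(sideTag == "m1" & reg == "arm", 0.8, 0),
                          1)
    acrRows[[sideTag]] <- data.table(
      chrom = genes[[paste0(sideTag, "_chrom")]][sel],
      start = st, end = st + 299L,  # 1-based closed
      acr_id = paste0("acr_", genes[[paste0(sideTag, "_gene")]][sel]),
      score = round(pmax(score, 0.1), 3),
      anc = sel)
  }
  other <- c(m1 = "m2", m2 = "m1")
  for (sideTag in c("m1", "m2")) {
    ar <- acrRows[[sideTag]]
    if (is.null(ar)) next
    sel <- ar$anc
    partnerKept <- retained[[other[[sideTag]]]][sel]
    homRows[[sideTag]] <- data.table(
      acr_id = ar$acr_id,
      subgenome = sideTag,
      partner_acr = ifelse(partnerKept,
                           paste0("acr_", genes[[paste0(other[[sideTag]],
                                                        "_gene")]][sel]),
                           NA_character_),
      sorghum_acr = sorAcr[sel],
      near_status = ifelse(genes$status[sel] == "pair", "wgd", "singleton"))
  }
  acrs <- copy(rbindlist(acrRows))[, anc := NULL][]
  acrsBed <- copy(acrs)[, start := start - 1L]  # BED is 0-based half-open
  fwrite(acrsBed, file.path(outDir, "acrs.bed"), sep = "\t",
         col.names = FALSE)
  addFile("acrs.bed", nrow(acrs))
  hom <- rbindlist(homRows)
  fwrite(hom, file.path(outDir, "acr_homology.tsv"), sep = "\t")
  addFile("acr_homology.tsv", nrow(hom))
  # loops: distal/proximal ACRs looping to their gene's TSS; sampling
  # weighted by accessibility, so maize1 arms are loop-enriched
  acrs2 <- rbindlist(acrRows)
  nLoops <- min(400L, nrow(acrs2))
  pick <- sample(seq_len(nrow(acrs2)), nLoops, prob = acrs2$score^2)
  loopSide <- ifelse(grepl("^acr_m1", acrs2$acr_id[pick]), "m1", "m2")
  tssCol <- paste0(loopSide, "_pos")
  tss <- vapply(seq_along(pick), function(z)
    genes[[tssCol[z]]][acrs2$anc[pick[z]]], numeric(1))
  loops <- data.table(
    chrom1 = acrs2$chrom[pick], start1 = acrs2$start[pick] - 1,
    end1 = acrs2$end[pick],
    chrom2 = acrs2$chrom[pick], start2 = pmax(0, round(tss) - 300),
    end2 = round(tss) + 300)
  fwrite(loops, file.path(outDir, "loops.bedpe"), sep = "\t",
         col.names = FALSE)
  addFile("loops.bedpe", nrow(loops))
  # --- ground truth for parameter recovery
  truth <- list(
    chromLengths = as.list(geom$chromLengths),
    peri = as.data.frame(geom$peri),
    centromere = data.frame(chrom = as.character(seqnames(geom$centromere)),
                            start = start(geom$centromere),
                            end = end(geom$centromere)),
    affected_pairs = genes$m1_gene[affected],
    n_pairs = nPairs,
    n_singleton_m1 = sum(genes$status == "singleton_m1"),
    n_singleton_m2 = sum(genes$status == "singleton_m2"),
    n_ancestral = nrow(genes),
    n_blocks = config@nBlocksPerChrom * geom$n,
    island_offset = config@islandOffset)
  jsonlite::write_json(truth, file.path(outDir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  addFile("truth.json", length(truth))
  man <- rbindlist(manifest)
  fwrite(man, file.path(outDir, "manifest.tsv"), sep = "\t")
  invisible(man)
}
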