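# Independent brute-force oracles, implemented from first principles and
# kept free of the package's lookup-table machinery.

GC_TABLE <- Biostrings::GENETIC_CODE

oracleTranslate <- function(codon) GC_TABLE[[codon]]

# all orderings of a set of positions, built by naive recursion
oraclePerms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (tail in oraclePerms(x[-i])) out[[length(out) + 1L]] <- c(x[i], tail)
  }
  out
}

# per-codon synonymous site count; mutations to stops are nonsynonymous
oracleSynSites <- function(codon) {
  aa <- oracleTranslate(codon)
  s <- 0
  for (p in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- nt
      if (oracleTranslate(alt) != "*" && oracleTranslate(alt) == aa)
        s <- s + 1 / 3
    }
  }
  s
}

# equal-weight pathway enumeration of (syn, nonsyn) differences
oraclePairDiff <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  sds <- c(); nds <- c(); blocked <- c()
  for (ord in oraclePerms(pos)) {
    cur <- c1; sd <- 0; nd <- 0; bl <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracleTranslate(nxt) == "*") bl <- TRUE
      if (oracleTranslate(nxt) != "*" &&
          oracleTranslate(nxt) == oracleTranslate(cur)) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    sds <- c(sds, sd); nds <- c(nds, nd); blocked <- c(blocked, bl)
  }
  use <- !blocked
  if (!any(use)) use <- rep(TRUE, length(sds))
  c(mean(sds[use]), mean(nds[use]))
}

oracleNG86 <- function(seq1, seq2) {
  n <- nchar(seq1)
  c1 <- substring(seq1, seq(1, n, 3), seq(3, n, 3))
  c2 <- substring(seq2, seq(1, n, 3), seq(3, n, 3))
  ok <- grepl("^[ACGT]{3}$", c1) & grepl("^[ACGT]{3}$", c2)
  c1 <- c1[ok]; c2 <- c2[ok]
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(c1)) {
    S <- S + (oracleSynSites(c1[i]) + oracleSynSites(c2[i])) / 2
    d <- oraclePairDiff(c1[i], c2[i])
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  N <- 3 * length(c1) - S
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  list(ka = jc(Nd / N), ks = jc(Sd / S), S = S, N = N, Sd = Sd, Nd = Nd)
}

# textbook Pearson chi-square
oracleChi2 <- function(tbl) {
  E <- outer(rowSums(tbl), colSums(tbl)) / sum(tbl)
  stat <- sum((tbl - E)^2 / E)
  list(statistic = stat, p.value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# paired t from the definition
oraclePairedT <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(statistic = t, p.value = 2 * stats::pt(-abs(t), n - 1))
}

# random sense-codon sequences for molevol tests
randomCodingSeq <- function(nCodons) {
  sense <- names(GC_TABLE)[GC_TABLE != "*"]
  paste(sample(sense, nCodons, replace = TRUE), collapse = "")
}

# apply k random single-nucleotide changes avoiding stops
mutateCoding <- function(seq, k) {
  n <- nchar(seq)
  for (z in seq_len(k)) {
    repeat {
      p <- sample.int(n, 1)
      nt <- sample(setdiff(c("A", "C", "G", "T"), substr(seq, p, p)), 1)
      cand <- seq
      substr(cand, p, p) <- nt
      cs <- 3 * ((p - 1) %/% 3) + 1
      if (oracleTranslate(substr(cand, cs, cs + 2)) != "*") {
        seq <- cand
        break
      }
    }
  }
  seq
}
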