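## Independent oracles and fixture builders used across test files.
## Everything here is deliberately written without reusing the package's
## internal helpers, so the tests compare two independent routes.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
  library(IRanges)
})

## reverse complement of a character string, independent of Biostrings
rcChar <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]),
        collapse = "")
}

## brute-force, position-by-position context classification of a genome
## string: returns a data.frame (pos, strand, label) covering all
## cytosines on both strands
bruteCensus <- function(seqStr) {
  n <- nchar(seqStr)
  at <- function(i) substr(seqStr, i, i)
  lab1 <- function(up, mid, down) {
    if (mid != "C") return(NA_character_)
    if (up %in% c("N", "") || down %in% c("N", "")) return("NONE")
    if (down == "G") {
      if (up == "G") return("CG_EXCLUDED_GCG")
      if (up == "C") return("CG_EXCLUDED_CCG")
      return("CG_KEPT")
    }
    if (up == "G") return("GC_KEPT")
    "NONE"
  }
  rows <- list()
  for (i in seq_len(n)) {
    b <- at(i)
    if (b == "C") {
      up <- if (i > 1) at(i - 1) else ""
      down <- if (i < n) at(i + 1) else ""
      rows[[length(rows) + 1L]] <-
        data.frame(pos = i, strand = "+", label = lab1(up, "C", down))
    }
    if (b == "G") {
      ## C on the minus strand; read 5'->3' on minus
      up <- if (i < n) chartr("ACGTN", "TGCAN", at(i + 1)) else ""
      down <- if (i > 1) chartr("ACGTN", "TGCAN", at(i - 1)) else ""
      rows[[length(rows) + 1L]] <-
        data.frame(pos = i, strand = "-", label = lab1(up, "C", down))
    }
  }
  do.call(rbind, rows)
}

## direct weighted-moment implementation of the weighted correlation
wpOracle <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  cxy <- sum(w * (x - mx) * (y - my)) / sw
  vx <- sum(w * (x - mx)^2) / sw
  vy <- sum(w * (y - my)^2) / sw
  cxy / sqrt(vx * vy)
}

## two-sided Fisher p-value by hypergeometric enumeration
fisherOracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

## random site calls on a toy chromosome
randomSiteCalls <- function(n, chromLen = 1000L, seed = 1L) {
  set.seed(seed)
  pos <- sort(sample.int(chromLen - 2L, n)) + 1L
  tot <- rpois(n, 4)
  m <- rbinom(n, tot, 0.5)
  tri <- paste0(sample(c("A", "G", "T"), n, TRUE), "C",
                sample(c("A", "G", "T"), n, TRUE))
  GRanges("chr1", IRanges(pos, width = 1L),
          strand = sample(c("+", "-"), n, TRUE),
          n_meth = m, n_unmeth = tot - m,
          context = sample(c("CpG", "GpC", "CpH"), n, TRUE),
          trinucleotide = tri)
}

## a small deterministic QC fixture: 20 cells, two planted ES failures
qcFixture <- function() {
  set.seed(2024)
  df <- data.frame(
    cell_id = sprintf("cell_%02d", 1:20),
    mapped_reads = round(runif(20, 5e5, 3e6)),
    mito_fraction = runif(20, 0.01, 0.12),
    genes_expressed = round(runif(20, 3000, 9000)),
    mapping_efficiency = runif(20, 0.15, 0.5),
    cpg_sites = round(runif(20, 8e5, 4e6)),
    gpc_sites = round(runif(20, 6e6, 3e7)),
    stringsAsFactors = FALSE
  )
  df$mapped_reads[3] <- 2e5       # fails ES min mapped reads
  df$mito_fraction[7] <- 0.16     # fails mitochondrial cap
  df$cpg_sites[11] <- 4e5         # fails ES CpG coverage
  df
}
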