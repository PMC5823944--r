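#' @importFrom Biostrings DNAStringSet reverseComplement
NULL

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.genomeChars <- function(genome, chrom) {
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not present in genome")
  strsplit(as.character(genome[[chrom]]), "", fixed = TRUE)[[1L]]
}

## Label cytosines from their flanking bases (already on the cytosine's own
## strand, 5'->3'). NA flanks (sequence edge) and non-ACGT flanks map to NONE.
.labelFlanks <- function(up, down) {
  lab <- rep("NONE", length(up))
  ok <- !is.na(up) & !is.na(down) & up %in% c("A", "C", "G", "T") &
    down %in% c("A", "C", "G", "T")
  cg <- ok & down == "G"
  lab[cg & up == "G"] <- "CG_EXCLUDED_GCG"
  lab[cg & up == "C"] <- "CG_EXCLUDED_CCG"
  lab[cg & up %in% c("A", "T")] <- "CG_KEPT"
  lab[ok & down != "G" & up == "G"] <- "GC_KEPT"
  lab
}

## Vectorised: flanking bases of cytosines at pos on the given strands of one
## chromosome character vector, read 5'->3' on the cytosine's strand.
.flanksAt <- function(ch, pos, strand) {
  L <- length(ch)
  up <- rep(NA_character_, length(pos))
  down <- up
  plus <- strand == "+"
  pin <- plus & pos > 1L
  up[pin] <- ch[pos[pin] - 1L]
  pin <- plus & pos < L
  down[pin] <- ch[pos[pin] + 1L]
  minus <- !plus
  min_ <- minus & pos < L
  up[min_] <- unname(.COMP[ch[pos[min_] + 1L]])
  min_ <- minus & pos > 1L
  down[min_] <- unname(.COMP[ch[pos[min_] - 1L]])
  list(up = up, down = down)
}

#' Classify a single cytosine by trinucleotide context
#'
#' The trinucleotide is read 5'->3' on the cytosine's own strand (for the
#' minus strand this is the reverse complement of the plus-strand window).
#' A-C-G and T-C-G feed the CpG methylation channel; G-C-A, G-C-C and G-C-T
#' feed the GpC accessibility channel; G-C-G is excluded from both channels
#' (endogenous and enzymatic methylation cannot be told apart) and C-C-G
#' from the CpG channel (enzyme off-target risk). Edge cytosines and
#' N-containing contexts classify as NONE.
#'
#' @param genome DNAStringSet.
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @param strand "+" or "-".
#' @return One of \code{\link{contextLabels}}.
#' @export
classifyCytosine <- function(genome, chrom, pos, strand) {
  ch <- .genomeChars(genome, chrom)
  if (pos < 1L || pos > length(ch))
    stop("position ", pos, " outside chromosome ", chrom)
  base <- if (strand == "+") ch[pos] else unname(.COMP[ch[pos]])
  if (is.na(base) || base != "C")
    stop("base at ", chrom, ":", pos, " (", strand, ") is not C")
  fl <- .flanksAt(ch, pos, strand)
  .labelFlanks(fl$up, fl$down)
}

.triFromFlanks <- function(up, down) {
  ifelse(is.na(up) | is.na(down), NA_character_, paste0(up, "C", down))
}

.deriveContext <- function(sites, genome) {
  lab <- rep(NA_character_, length(sites))
  tri <- lab
  for (chrom in unique(as.character(seqnames(sites)))) {
    sel <- as.character(seqnames(sites)) == chrom
    ch <- .genomeChars(genome, chrom)
    fl <- .flanksAt(ch, start(sites)[sel], as.character(strand(sites))[sel])
    lab[sel] <- .labelFlanks(fl$up, fl$down)
    tri[sel] <- .triFromFlanks(fl$up, fl$down)
  }
  sites$trinucleotide <- tri
  sites$context <- c(CG_KEPT = "CpG", CG_EXCLUDED_GCG = "CpG",
                     CG_EXCLUDED_CCG = "CpG", GC_KEPT = "GpC",
                     NONE = "CpH")[lab]
  sites
}

#' Split site calls into CpG methylation and GpC accessibility channels
#'
#' Reclassifies every call against the genome sequence (the report's stored
#' trinucleotide is advisory) and partitions: CG_KEPT calls to the CpG
#' (methylation) output, GC_KEPT calls to the GpC (accessibility) output,
#' everything else discarded and tallied. The two outputs are disjoint by
#' construction and together with the discard census cover the input.
#'
#' @param sites GRanges of site calls.
#' @param genome DNAStringSet; required unless \code{trustReport}.
#' @param onMismatch behaviour when a stored trinucleotide disagrees with
#'   the genome: warn and trust the genome (default) or error.
#' @param trustReport if TRUE, classify from the stored trinucleotide
#'   without genome lookup.
#' @return List with elements \code{cpg}, \code{gpc} (GRanges) and
#'   \code{census} (named integer counts per context label).
#' @export
partitionReport <- function(sites, genome = NULL,
                            onMismatch = c("warn", "error"),
                            trustReport = FALSE) {
  onMismatch <- match.arg(onMismatch)
  validateSiteCalls(sites)
  if (trustReport) {
    tri <- sites$trinucleotide
    up <- substr(tri, 1L, 1L)
    down <- substr(tri, 3L, 3L)
    lab <- .labelFlanks(up, down)
  } else {
    if (is.null(genome))
      stop("genome is required unless trustReport = TRUE")
    lab <- rep("NONE", length(sites))
    for (chrom in unique(as.character(seqnames(sites)))) {
      sel <- which(as.character(seqnames(sites)) == chrom)
      ch <- .genomeChars(genome, chrom)
      pos <- start(sites)[sel]
      str <- as.character(strand(sites))[sel]
      base <- ifelse(str == "+", ch[pos], unname(.COMP[ch[pos]]))
      if (any(base != "C", na.rm = TRUE)) {
        i <- sel[which(base != "C")[1L]]
        stop("call at ", seqnames(sites)[i], ":", start(sites)[i],
             " (", strand(sites)[i], ") is not a cytosine in the genome")
      }
      fl <- .flanksAt(ch, pos, str)
      lab[sel] <- .labelFlanks(fl$up, fl$down)
      tri <- .triFromFlanks(fl$up, fl$down)
      stored <- sites$trinucleotide[sel]
      bad <- !is.na(stored) & !is.na(tri) & nchar(stored) == 3L &
        stored != tri
      if (any(bad)) {
        msg <- paste0(sum(bad), " call(s) on ", chrom,
                      " carry a trinucleotide that disagrees with the genome")
        if (onMismatch == "error") stop(msg)
        warning(msg, "; trusting the genome")
      }
    }
  }
  census <- vapply(contextLabels(), function(l) sum(lab == l), integer(1))
  list(cpg = sites[lab == "CG_KEPT"],
       gpc = sites[lab == "GC_KEPT"],
       census = census)
}

#' Exhaustive trinucleotide census of a genome
#'
#' Scans every cytosine on both strands, classifies each into the NOMe
#' context labels, and additionally reports CpG and GpC dinucleotide totals
#' and the mean spacing between consecutive GpC dinucleotide starts per
#' chromosome (the quantity behind the roughly 1-in-16-bp resolution of
#' GpC-based accessibility footprinting).
#'
#' @param genome DNAStringSet.
#' @return A \linkS4class{ContextCensus}.
#' @export
contextCensus <- function(genome) {
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L)
    stop("empty genome")
  labs <- contextLabels()
  counts <- matrix(0L, nrow = length(labs), ncol = 2L,
                   dimnames = list(labs, c("+", "-")))
  cpg <- 0
  gpc <- 0
  spacing <- numeric(0)
  for (chrom in names(genome)) {
    ch <- .genomeChars(genome, chrom)
    L <- length(ch)
    if (L == 0L) next
    for (str in c("+", "-")) {
      pos <- if (str == "+") which(ch == "C") else which(ch == "G")
      if (!length(pos)) next
      fl <- .flanksAt(ch, pos, rep(str, length(pos)))
      lab <- .labelFlanks(fl$up, fl$down)
      tab <- table(factor(lab, levels = labs))
      counts[, str] <- counts[, str] + as.integer(tab)
    }
    if (L >= 2L) {
      cpg <- cpg + sum(ch[-L] == "C" & ch[-1L] == "G")
      gstarts <- which(ch[-L] == "G" & ch[-1L] == "C")
      gpc <- gpc + length(gstarts)
      spacing[chrom] <- if (length(gstarts) >= 2L) mean(diff(gstarts))
                        else NA_real_
    } else spacing[chrom] <- NA_real_
  }
  new("ContextCensus", counts = counts,
      dinucleotides = c(CpG = cpg, GpC = gpc),
      gpcSpacing = spacing, nScanned = sum(counts))
}

#' Derived fractions from a context census
#'
#' @param census a \linkS4class{ContextCensus}.
#' @return Named numeric: fraction of CpG-context cytosines excluded as
#'   G-C-G and as C-C-G, the fraction kept, and the genome-wide mean GpC
#'   spacing in bp.
#' @export
censusFractions <- function(census) {
  cg <- rowSums(census@counts)[c("CG_KEPT", "CG_EXCLUDED_GCG",
                                 "CG_EXCLUDED_CCG")]
  tot <- sum(cg)
  c(frac_cpg_gcg = unname(cg["CG_EXCLUDED_GCG"] / tot),
    frac_cpg_ccg = unname(cg["CG_EXCLUDED_CCG"] / tot),
    frac_cpg_kept = unname(cg["CG_KEPT"] / tot),
    mean_gpc_spacing = mean(census@gpcSpacing, na.rm = TRUE))
}
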