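#' Configuration of the synthetic single-cell NOMe-seq generator
#'
#' The generator emulates the data model the analyses assume: per-cell
#' nucleosome arrays with a fixed repeat length and per-cell jitter;
#' nucleosome-depleted regions (NDRs) at active promoters whose openness is
#' driven by a per-(cell, gene) latent accessibility factor; endogenous CpG
#' methylation with beta-distributed locus means and cell deviations
#' anti-correlated with accessibility; expression negative-binomially
#' distributed with a mean coupled to the promoter's epigenetic state; and
#' binomial read sampling with a small symmetric bisulfite conversion
#' error.
#'
#' The default condition is a 40-cell population over 100 promoter loci, 20
#' of which carry genuine methylation-expression coupling of latent
#' strength -0.8, with a genome-wide methylation-accessibility coupling of
#' -0.5 and nucleosome repeat length 190 bp.
#'
#' @param nCells number of cells.
#' @param genomeLength genome length in bp (single chromosome).
#' @param baseComposition named probabilities for A, C, G, T.
#' @param nGenes genes placed at regular intervals along the genome.
#' @param nLoci number of feature loci for the rate-level generator.
#' @param contexts context labels cycled over the loci.
#' @param nCoupledLoci loci with genuine methylation-expression coupling.
#' @param coupledR latent methylation-expression correlation at coupled
#'   loci (<= 0).
#' @param rhoMA,rhoME,rhoAE latent couplings: methylation-accessibility
#'   (<= 0), methylation-expression (<= 0), accessibility-expression
#'   (>= 0).
#' @param rhoMAEnd if non-NULL, rhoMA ramps linearly from \code{rhoMA} at
#'   pseudotime 0 to \code{rhoMAEnd} at pseudotime 1.
#' @param subpopProportions mixture proportions; length 2 draws pseudotime
#'   from a bimodal mixture (two subpopulations), length 1 from
#'   Uniform(0,1).
#' @param nucleosomeRepeat nucleosome repeat length in bp.
#' @param nucleosomeJitterSd per-cell jitter of dyad spacing in bp.
#' @param ndrWidth width of the promoter NDR in bp.
#' @param ndrOpenStart,ndrOpenEnd probability that a promoter NDR is open
#'   at pseudotime 0 and 1.
#' @param accHigh,accLow GpC accessibility emission probability in
#'   linker/NDR versus nucleosome-occupied DNA.
#' @param methLocusShape1,methLocusShape2 beta shape parameters of
#'   promoter methylation locus means.
#' @param methLogitSd cell-deviation scale of methylation on the logit
#'   scale.
#' @param bgMethMean,bgMethConc background (non-promoter) CpG methylation
#'   beta mean and concentration.
#' @param siteCoverageProb probability a cytosine is covered in a cell.
#' @param readDepth mean reads per covered site.
#' @param featureMeanSites mean covered sites per feature locus for the
#'   rate-level generator.
#' @param featureCoverProb probability a feature locus is observed in a
#'   cell (rate-level generator).
#' @param exprBaseLog2 baseline log2 expression mean.
#' @param exprTrajAmp amplitude of smooth pseudotime trends on expression.
#' @param nbSize negative-binomial size (inverse dispersion).
#' @param conversionError symmetric bisulfite conversion flip probability.
#' @param trajectory if TRUE, half of the genes carry smooth expression
#'   trends along pseudotime and gene 1 is a decreasing marker.
#' @return A validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(nCells = 40L, genomeLength = 50000L,
                      baseComposition = c(A = 0.25, C = 0.25, G = 0.25,
                                          T = 0.25),
                      nGenes = 20L, nLoci = 100L,
                      contexts = c("promoter", "gene_body"),
                      nCoupledLoci = 20L, coupledR = -0.8,
                      rhoMA = -0.5, rhoME = -0.3, rhoAE = 0.3,
                      rhoMAEnd = NULL,
                      subpopProportions = 1,
                      nucleosomeRepeat = 190, nucleosomeJitterSd = 10,
                      ndrWidth = 150, ndrOpenStart = 0.8, ndrOpenEnd = 0.8,
                      accHigh = 0.8, accLow = 0.1,
                      methLocusShape1 = 2, methLocusShape2 = 2,
                      methLogitSd = 1.5,
                      bgMethMean = 0.7, bgMethConc = 10,
                      siteCoverageProb = 0.3, readDepth = 5,
                      featureMeanSites = 5, featureCoverProb = 0.8,
                      exprBaseLog2 = 5, exprTrajAmp = 3, nbSize = 10,
                      conversionError = 0.005, trajectory = FALSE) {
  params <- as.list(environment())
  cfg <- new("SimConfig", params = params)
  ## joint feasibility: the implied 3x3 latent correlation matrix must be
  ## positive semi-definite
  det3 <- 1 + 2 * rhoMA * rhoME * rhoAE - rhoMA^2 - rhoME^2 - rhoAE^2
  if (det3 < -1e-9)
    stop("contradictory couplings: (rhoMA, rhoME, rhoAE) do not form a ",
         "valid correlation structure")
  validObject(cfg)
  cfg
}

#' @rdname simConfig
#' @param x a SimConfig.
#' @param name parameter name.
#' @export
setMethod("$", "SimConfig", function(x, name) x@params[[name]])

#' Simulate a genome with regularly spaced genes
#'
#' Bases are drawn i.i.d. at the configured composition; genes of 2 kb are
#' placed at regular intervals (plus strand, TSS at the gene start) and
#' returned as an annotation.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param seed RNG seed; the same seed yields byte-identical output.
#' @return List with \code{genome} (DNAStringSet, one chromosome) and
#'   \code{genes} (GRanges with gene_id).
#' @export
simulateGenome <- function(config, seed = 1L) {
  set.seed(seed)
  p <- config@params
  comp <- p$baseComposition / sum(p$baseComposition)
  bases <- sample(names(comp), p$genomeLength, replace = TRUE, prob = comp)
  genome <- DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- "chr1"
  spacing <- p$genomeLength %/% (p$nGenes + 1L)
  geneLen <- min(2000L, max(200L, spacing %/% 2L))
  tss <- spacing * seq_len(p$nGenes)
  genes <- GRanges("chr1", IRanges(tss, width = geneLen), strand = "+",
                   gene_id = paste0("gene_", seq_len(p$nGenes)))
  list(genome = genome, genes = genes)
}

#' Simulate per-cell pseudotime and subpopulation state
#'
#' With a single subpopulation, pseudotime is Uniform(0,1); with two, it is
#' drawn from a bimodal beta mixture (Beta(2,8) and Beta(8,2)) so the
#' populations separate along the trajectory.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param seed RNG seed.
#' @return data.frame with cell_id, tau, subpop.
#' @export
simulateTrajectory <- function(config, seed = 1L) {
  set.seed(seed)
  p <- config@params
  n <- p$nCells
  stopifnot(n >= 10L)
  props <- p$subpopProportions / sum(p$subpopProportions)
  if (length(props) >= 2L) {
    comp <- sample(seq_along(props), n, replace = TRUE, prob = props)
    tau <- ifelse(comp == 1L, rbeta(n, 2, 8), rbeta(n, 8, 2))
  } else {
    comp <- rep(1L, n)
    tau <- runif(n)
  }
  data.frame(cell_id = sprintf("cell_%02d", seq_len(n)), tau = tau,
             subpop = comp, stringsAsFactors = FALSE)
}

.rhoAt <- function(p, tau) {
  if (is.null(p$rhoMAEnd)) rep(p$rhoMA, length(tau))
  else p$rhoMA + (p$rhoMAEnd - p$rhoMA) * tau
}

#' Rate-level synthetic dataset (feature rates, expression, truth)
#'
#' Generates the latent layer of the full simulator directly at feature
#' resolution: per-(cell, locus) latent methylation, accessibility and
#' expression factors with the configured couplings, then binomial read
#' sampling into \linkS4class{RateMatrix} objects and negative-binomial
#' expression counts. Loci are assigned context labels cyclically and each
#' locus is associated with one gene. This is the generator used for the
#' statistical recovery and calibration experiments; the site-level
#' generator (\code{\link{simulateCells}}) feeds the sequence-facing
#' modules.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param seed RNG seed.
#' @return List: \code{met}, \code{acc} (RateMatrix), \code{logcounts}
#'   (genes x cells), \code{counts}, \code{features} (GRanges),
#'   \code{truth} (list with tau, zE, zM, zA, coupled, rho).
#' @export
simulateFeatureRates <- function(config, seed = 1L) {
  p <- config@params
  traj <- simulateTrajectory(config, seed)
  set.seed(seed + 1L)
  nC <- p$nCells
  nL <- p$nLoci
  cells <- traj$cell_id
  loci <- sprintf("locus_%03d", seq_len(nL))
  genes <- sprintf("gene_%03d", seq_len(nL))
  ctx <- rep_len(p$contexts, nL)
  rho <- .rhoAt(p, traj$tau)
  coupled <- seq_len(nL) <= p$nCoupledLoci

  ## loci sit on a continuum of between-cell heterogeneity, and coupling
  ## lives at its variable end: a locus whose epigenetic state switches
  ## between cells is exactly the kind that can couple to expression,
  ## while stable loci have nothing to correlate. This is what makes
  ## independent filtering informative rather than a coin flip.
  scaleM <- p$methLogitSd / 1.5
  sdM <- runif(nL, 0.2, 1.4) * scaleM
  sdM[coupled] <- runif(sum(coupled), 1.2, 1.8) * scaleM
  exprSlope <- runif(nL, 0.3, 1.5)
  exprSlope[coupled] <- runif(sum(coupled), 1.2, 1.8)

  zE <- matrix(rnorm(nL * nC), nL, nC)
  xi <- matrix(rnorm(nL * nC), nL, nC)
  zeta <- matrix(rnorm(nL * nC), nL, nC)
  rME <- ifelse(coupled, p$coupledR, 0)
  zM <- rME * zE + sqrt(1 - rME^2) * xi
  zA <- sweep(zM, 2, rho, "*") +
    sweep(zeta, 2, sqrt(1 - rho^2), "*")

  muM <- rbeta(nL, p$methLocusShape1, p$methLocusShape2)
  muM <- pmin(0.95, pmax(0.05, muM))
  ## a locus that switches state across cells has an intermediate mean
  muM[coupled] <- runif(sum(coupled), 0.35, 0.65)
  muA <- pmin(0.95, pmax(0.05, rbeta(nL, 2, 2)))
  rateM <- plogis(qlogis(muM) + sdM * zM)
  rateA <- plogis(qlogis(muA) + sdM * zA)

  sampleLayer <- function(latent, layer) {
    obs <- matrix(runif(nL * nC) < p$featureCoverProb, nL, nC)
    nSites <- matrix(0L, nL, nC)
    nSites[obs] <- 1L + rpois(sum(obs), p$featureMeanSites - 1)
    nReads <- nSites * p$readDepth
    m <- matrix(0L, nL, nC)
    m[obs] <- rbinom(sum(obs), nReads[obs], latent[obs])
    rate <- ifelse(obs, m / pmax(nReads, 1L), NA_real_)
    a <- m + 1
    b <- nReads - m + 1
    se <- ifelse(obs, sqrt(a * b / ((a + b)^2 * (a + b + 1))), NA_real_)
    dimnames(rate) <- list(loci, cells)
    dimnames(se) <- dimnames(rate)
    dimnames(nSites) <- dimnames(rate)
    feat <- GRanges("chr1", IRanges(1000L + 5000L * seq_len(nL) -
                                      1000L, width = 2000L),
                    feature_id = loci, context_class = ctx,
                    gene_id = genes)
    se2 <- SummarizedExperiment(
      assays = list(rate = rate, se = se, nSites = nSites),
      rowRanges = feat)
    metadata(se2)$layer <- layer
    new("RateMatrix", se2)
  }
  met <- sampleLayer(rateM, "met")
  acc <- sampleLayer(rateA, "acc")

  trajAmp <- if (isTRUE(p$trajectory)) p$exprTrajAmp else 0
  phase <- runif(nL, 0, 1)
  trendOn <- seq_len(nL) %% 2L == 0L
  trend <- matrix(0, nL, nC)
  if (trajAmp > 0) {
    for (i in which(trendOn))
      trend[i, ] <- trajAmp * sin(pi * (traj$tau + phase[i]))
    trend[1L, ] <- trajAmp * (1 - traj$tau) * 2   # decreasing marker
  }
  logMean <- p$exprBaseLog2 + exprSlope * zE + trend +
    2 * p$rhoAE * zA + 2 * p$rhoME * zM
  counts <- matrix(rnbinom(nL * nC, mu = 2^logMean, size = p$nbSize),
                   nL, nC, dimnames = list(genes, cells))
  storage.mode(counts) <- "integer"
  logcounts <- normalizeExpression(counts)$logcounts

  list(met = met, acc = acc, counts = counts, logcounts = logcounts,
       features = rowRanges(met),
       truth = list(tau = setNames(traj$tau, cells), zE = zE, zM = zM,
                    zA = zA, coupled = coupled, sdM = sdM,
                    exprSlope = exprSlope, rho = rho,
                    rateM = rateM, rateA = rateA,
                    marker = if (trajAmp > 0) genes[1L] else NA_character_))
}

## occupancy: TRUE where a position lies within 73 bp of a nucleosome dyad
.occupied <- function(pos, dyads) {
  if (!length(dyads)) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos, dyads)
  dLeft <- ifelse(idx >= 1L, pos - dyads[pmax(idx, 1L)], Inf)
  dRight <- ifelse(idx < length(dyads), dyads[pmin(idx + 1L,
                                                   length(dyads))] - pos,
                   Inf)
  pmin(dLeft, dRight) <= 73
}

#' Site-level synthetic single-cell NOMe-seq dataset
#'
#' Emits per-cell Bismark-style cytosine reports covering all trinucleotide
#' contexts (partitioning is the pipeline's job), an expression count
#' table, a per-cell QC statistics table, and full ground truth. Per cell,
#' nucleosome dyads are tiled at the configured repeat length with
#' per-cell jitter; promoter NDRs open with a probability interpolating
#' between the configured endpoints along pseudotime, driven by the same
#' latent factor that couples to methylation and expression; GpC
#' accessibility emits at the high rate in linker/NDR positions and the
#' low rate under nucleosomes; CpG methylation follows locus means with
#' logit-scale cell deviations; reads are binomial with a symmetric
#' conversion-error flip.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param genome,genes output of \code{\link{simulateGenome}}.
#' @param seed RNG seed; per-cell streams are derived deterministically.
#' @param emitRegions optional GRanges restricting which cytosines are
#'   emitted (for speed); default is the whole genome.
#' @return List: \code{reports} (named list of site-call GRanges),
#'   \code{counts}, \code{qcStats} (data.frame), \code{truth} (list:
#'   traj, dyads, ndrOpen, zA, zM, rateM per gene).
#' @export
simulateCells <- function(config, genome, genes, seed = 1L,
                          emitRegions = NULL) {
  p <- config@params
  traj <- simulateTrajectory(config, seed)
  nC <- p$nCells
  L <- length(genome[[1L]])
  ch <- .genomeChars(genome, "chr1")

  ## all cytosines on both strands, with genome-derived context
  posP <- which(ch == "C")
  posM <- which(ch == "G")
  allPos <- c(posP, posM)
  allStr <- rep(c("+", "-"), c(length(posP), length(posM)))
  if (!is.null(emitRegions)) {
    keep <- rep(FALSE, length(allPos))
    for (i in seq_along(emitRegions))
      keep <- keep | (allPos >= start(emitRegions)[i] &
                        allPos <= end(emitRegions)[i])
    allPos <- allPos[keep]
    allStr <- allStr[keep]
  }
  fl <- .flanksAt(ch, allPos, allStr)
  lab <- .labelFlanks(fl$up, fl$down)
  tri <- .triFromFlanks(fl$up, fl$down)
  ctxCol <- c(CG_KEPT = "CpG", CG_EXCLUDED_GCG = "CpG",
              CG_EXCLUDED_CCG = "CpG", GC_KEPT = "GpC", NONE = "CpH")[lab]

  tss <- ifelse(as.character(strand(genes)) == "-", end(genes),
                start(genes))
  nG <- length(genes)
  promHalf <- 2000L
  geneOfSite <- rep(NA_integer_, length(allPos))
  for (g in seq_len(nG)) {
    sel <- allPos >= tss[g] - promHalf & allPos <= tss[g] + promHalf
    geneOfSite[sel] <- g
  }

  set.seed(seed + 7L)
  ## reference nucleosome grid shared by all cells (phased array); each
  ## cell jitters the dyad positions so pseudo-bulk keeps the repeat-length
  ## periodicity while single cells differ
  refDyads <- runif(1, 0, p$nucleosomeRepeat) +
    p$nucleosomeRepeat * seq(0, ceiling(L / p$nucleosomeRepeat) + 1L)
  muM <- pmin(0.95, pmax(0.05, rbeta(nG, p$methLocusShape1,
                                     p$methLocusShape2)))
  bgA <- p$bgMethMean * p$bgMethConc
  bgB <- (1 - p$bgMethMean) * p$bgMethConc
  bgRate <- rbeta(length(allPos), bgA, bgB)

  rho <- .rhoAt(p, traj$tau)
  pOpen <- p$ndrOpenStart + (p$ndrOpenEnd - p$ndrOpenStart) * traj$tau

  reports <- vector("list", nC)
  names(reports) <- traj$cell_id
  dyadsList <- vector("list", nC)
  zAm <- matrix(NA_real_, nG, nC)
  zMm <- matrix(NA_real_, nG, nC)
  openM <- matrix(FALSE, nG, nC)
  e <- p$conversionError

  for (i in seq_len(nC)) {
    set.seed(seed + 1000L + i)
    ## per-cell jitter of the shared phased array
    dyads <- sort(refDyads + rnorm(length(refDyads), 0,
                                   p$nucleosomeJitterSd))
    dyads <- dyads[dyads <= L + p$nucleosomeRepeat]
    ## promoter latent factors and NDR state
    zA <- rnorm(nG)
    zM <- rho[i] * zA + sqrt(1 - rho[i]^2) * rnorm(nG)
    open <- zA > qnorm(1 - pOpen[i])
    zAm[, i] <- zA
    zMm[, i] <- zM
    openM[, i] <- open
    for (g in which(open)) {
      inNdr <- dyads >= tss[g] - p$ndrWidth / 2 &
        dyads <= tss[g] + p$ndrWidth / 2
      dyads <- dyads[!inNdr]
    }
    for (g in which(!open)) {
      ## a closed promoter carries a positioned nucleosome at the TSS
      if (!any(abs(dyads - tss[g]) <= p$ndrWidth / 2))
        dyads <- sort(c(dyads, tss[g]))
    }
    dyadsList[[i]] <- dyads

    covered <- which(runif(length(allPos)) < p$siteCoverageProb)
    pos <- allPos[covered]
    occ <- .occupied(pos, dyads)
    accP <- ifelse(occ, p$accLow, p$accHigh)
    g <- geneOfSite[covered]
    methP <- bgRate[covered]
    inProm <- !is.na(g)
    methP[inProm] <- plogis(qlogis(muM[g[inProm]]) +
                              p$methLogitSd * zM[g[inProm]])
    labC <- lab[covered]
    prob <- rep(0.01, length(covered))          # CpH / NONE background
    prob[labC == "CG_KEPT"] <- methP[labC == "CG_KEPT"]
    prob[labC == "CG_EXCLUDED_CCG"] <- methP[labC == "CG_EXCLUDED_CCG"]
    prob[labC == "GC_KEPT"] <- accP[labC == "GC_KEPT"]
    gcg <- labC == "CG_EXCLUDED_GCG"            # both signals superimpose
    prob[gcg] <- 1 - (1 - methP[gcg]) * (1 - accP[gcg])
    prob <- prob * (1 - e) + (1 - prob) * e
    nReads <- 1L + rpois(length(covered), p$readDepth - 1)
    m <- rbinom(length(covered), nReads, prob)
    gr <- GRanges(rep("chr1", length(pos)), IRanges(pos, width = 1L),
                  strand = allStr[covered],
                  n_meth = m, n_unmeth = nReads - m,
                  context = ctxCol[covered],
                  trinucleotide = tri[covered])
    reports[[i]] <- gr[order(start(gr), as.character(strand(gr)))]
  }

  ## expression coupled to promoter state
  set.seed(seed + 31L)
  trajAmp <- if (isTRUE(p$trajectory)) p$exprTrajAmp else 0
  trend <- matrix(0, nG, nC)
  if (trajAmp > 0) {
    phase <- runif(nG)
    for (g in seq_len(nG))
      if (g %% 2L == 0L)
        trend[g, ] <- trajAmp * sin(pi * (traj$tau + phase[g]))
    trend[1L, ] <- trajAmp * 2 * (1 - traj$tau)
  }
  logMean <- p$exprBaseLog2 + trend + 2 * p$rhoAE * zAm + 2 * p$rhoME * zMm
  counts <- matrix(rnbinom(nG * nC, mu = 2^logMean, size = p$nbSize),
                   nG, nC, dimnames = list(genes$gene_id, traj$cell_id))
  storage.mode(counts) <- "integer"

  ## per-cell QC statistics at realistic magnitudes
  set.seed(seed + 63L)
  qcStats <- data.frame(
    cell_id = traj$cell_id,
    mapped_reads = round(exp(rnorm(nC, log(1.2e6), 0.5))),
    mito_fraction = rbeta(nC, 2, 25),
    genes_expressed = pmax(colSums(counts > 0) * 150L, 1L),
    mapping_efficiency = runif(nC, 0.2, 0.5),
    cpg_sites = round(exp(rnorm(nC, log(1.5e6), 0.4))),
    gpc_sites = round(exp(rnorm(nC, log(1.2e7), 0.4))),
    stringsAsFactors = FALSE
  )

  list(reports = reports, counts = counts, qcStats = qcStats,
       truth = list(traj = traj, dyads = dyadsList, ndrOpen = openM,
                    zA = zAm, zM = zMm, muM = muM, tss = tss,
                    logMean = logMean))
}

#' Simulate TSS accessibility profiles whose shape (not rate) drives
#' expression
#'
#' Generates per-(cell, gene) GpC observations in a scaled TSS window in
#' which the depth of the nucleosome-depleted region varies while the
#' window-average accessibility stays constant: the emission probability is
#' \code{0.5 + d (exp(-x^2/(2 w^2)) - c0)} with c0 the window mean of the
#' Gaussian bump, so the NDR depth d is encoded purely in the profile
#' shape. Expression is a linear function of d plus noise. Used to compare
#' profile-based against rate-based expression prediction.
#'
#' @param nCells,nGenes dimensions.
#' @param nSites covered GpC sites per window.
#' @param reads reads per site.
#' @param ndrSd half-width of the NDR bump on the scaled axis.
#' @param exprNoiseSd residual expression noise (log2 units).
#' @param seed RNG seed.
#' @return List: \code{pdata} (per gene: per cell data.frames x/m/n),
#'   \code{expr} (genes x cells log2 expression), \code{depth} (genes x
#'   cells latent NDR depth).
#' @export
simulateProfileDataset <- function(nCells = 25L, nGenes = 50L,
                                   nSites = 15L, reads = 3L,
                                   ndrSd = 0.3, exprNoiseSd = 0.3,
                                   seed = 1L) {
  set.seed(seed)
  cells <- sprintf("cell_%02d", seq_len(nCells))
  genes <- sprintf("gene_%03d", seq_len(nGenes))
  c0 <- mean(exp(-seq(-1, 1, length.out = 401)^2 / (2 * ndrSd^2)))
  depth <- matrix(runif(nGenes * nCells, -0.45, 0.45), nGenes, nCells,
                  dimnames = list(genes, cells))
  pdata <- lapply(seq_len(nGenes), function(g) {
    out <- lapply(seq_len(nCells), function(j) {
      x <- sort(runif(nSites, -1, 1))
      pr <- 0.5 + depth[g, j] * (exp(-x^2 / (2 * ndrSd^2)) - c0)
      pr <- pmin(0.99, pmax(0.01, pr))
      data.frame(x = x, m = rbinom(nSites, reads, pr), n = reads)
    })
    names(out) <- cells
    out
  })
  names(pdata) <- genes
  expr <- 5 + 6 * depth + matrix(rnorm(nGenes * nCells, 0, exprNoiseSd),
                                 nGenes, nCells)
  dimnames(expr) <- dimnames(depth)
  list(pdata = pdata, expr = expr, depth = depth)
}

#' Simulate a labelled mixture of single-cell accessibility profiles
#'
#' Cells are split evenly among K well-separated prototype profiles (open
#' TSS, closed TSS, and a shifted +1-nucleosome pattern) and GpC
#' observations are drawn binomially from the prototype curve. Used for
#' cluster-number and assignment recovery experiments.
#'
#' @param nCells number of cells.
#' @param K true number of clusters (1 to 3).
#' @param nSites covered sites per cell.
#' @param reads reads per site.
#' @param seed RNG seed.
#' @return List: \code{pdata} (per-cell data.frames x/m/n) and
#'   \code{labels} (true cluster per cell).
#' @export
simulateProfileMixture <- function(nCells = 40L, K = 2L, nSites = 15L,
                                   reads = 4L, seed = 1L) {
  stopifnot(K >= 1L, K <= 3L)
  set.seed(seed)
  protos <- list(
    function(x) 0.2 + 0.7 * exp(-x^2 / 0.18),          # open TSS
    function(x) 0.85 - 0.7 * exp(-x^2 / 0.18),         # closed TSS
    function(x) 0.5 + 0.4 * sin(pi * x)                # shifted nucleosome
  )
  labels <- rep_len(seq_len(K), nCells)
  pdata <- lapply(seq_len(nCells), function(i) {
    x <- sort(runif(nSites, -1, 1))
    pr <- pmin(0.95, pmax(0.05, protos[[labels[i]]](x)))
    data.frame(x = x, m = rbinom(nSites, reads, pr), n = reads)
  })
  names(pdata) <- sprintf("cell_%02d", seq_len(nCells))
  list(pdata = pdata, labels = setNames(labels, names(pdata)))
}

#' Write a simulated dataset to disk
#'
#' Emits genome.fa, genes.bed, per-cell cytosine reports
#' (\code{<cell>.cov.tsv}), counts.tsv, cells_qc.tsv and truth tables under
#' the given directory.
#'
#' @param sim output of \code{\link{simulateCells}}.
#' @param genome,genes output of \code{\link{simulateGenome}}.
#' @param dir output directory (created if needed).
#' @return Invisibly the directory.
#' @export
writeSimulatedDataset <- function(sim, genome, genes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
  writeFeaturesBed(
    GRanges(seqnames(genes), IRanges(start(genes), end(genes)),
            feature_id = genes$gene_id),
    file.path(dir, "genes.bed"))
  for (cell in names(sim$reports))
    writeCytosineReport(sim$reports[[cell]],
                        file.path(dir, paste0(cell, ".cov.tsv")))
  writeExpressionCounts(sim$counts, file.path(dir, "counts.tsv"))
  write.table(sim$qcStats, file.path(dir, "cells_qc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  write.table(sim$truth$traj, file.path(tdir, "trajectory.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @importFrom stats plogis qlogis rlnorm
NULL
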