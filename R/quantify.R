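#' @importFrom stats var median pnorm qnorm dbeta p.adjust pt cor cor.test
#'   rbinom rnorm runif rbeta rpois rnbinom sd quantile optim prcomp
NULL

#' Estimate a beta prior for per-site rates
#'
#' Method-of-moments fit of a beta distribution to the observed site-level
#' proportions of one cell and layer. The raw variance of proportions is
#' corrected for binomial sampling noise using the per-site read counts
#' before matching moments, so the prior reflects biological spread rather
#' than shallow coverage. Degenerate inputs (no spread, or spread at the
#' binomial maximum) fall back to the flat Beta(1,1) prior with a warning.
#' Returned hyperparameters are clipped to be >= 1 so the posterior mode is
#' interior.
#'
#' @param nMeth,nTotal integer vectors of methylated and total read counts.
#' @param method "mom" (default) or "flat" for Beta(1,1).
#' @return Named numeric \code{c(alpha, beta)}.
#' @export
estimateBetaPrior <- function(nMeth, nTotal, method = c("mom", "flat")) {
  method <- match.arg(method)
  if (method == "flat") return(c(alpha = 1, beta = 1))
  keep <- nTotal >= 1L
  nMeth <- nMeth[keep]
  nTotal <- nTotal[keep]
  if (length(nTotal) < 10L) {
    warning("fewer than 10 covered sites; using flat prior")
    return(c(alpha = 1, beta = 1))
  }
  p <- nMeth / nTotal
  mu <- mean(p)
  vRaw <- var(p)
  cc <- mean(1 / nTotal)
  v <- (vRaw - mu * (1 - mu) * cc) / (1 - cc)
  if (!is.finite(v) || v <= 0 || v >= mu * (1 - mu) || mu <= 0 || mu >= 1) {
    warning("degenerate proportion spread; using flat prior")
    return(c(alpha = 1, beta = 1))
  }
  s <- mu * (1 - mu) / v - 1
  c(alpha = max(1, mu * s), beta = max(1, (1 - mu) * s))
}

#' Per-site MAP rate under a beta-binomial model
#'
#' Each site's reads are modelled as Binomial(nTotal, theta) with a
#' Beta(alpha, beta) prior on theta. The returned rate is the maximum a
#' posteriori estimate (posterior mode), clipped to [0,1]; the standard
#' error is the posterior standard deviation of
#' Beta(nMeth + alpha, nTotal - nMeth + beta). Zero-coverage sites yield
#' NA (missing), not an error.
#'
#' @param nMeth,nTotal integer vectors.
#' @param alpha,beta prior hyperparameters, each >= 1.
#' @return data.frame with columns rate, se, n_total.
#' @export
siteRate <- function(nMeth, nTotal, alpha = 1, beta = 1) {
  stopifnot(alpha >= 1, beta >= 1, all(nMeth <= nTotal), all(nMeth >= 0))
  a <- nMeth + alpha
  b <- nTotal - nMeth + beta
  denom <- nTotal + alpha + beta - 2
  rate <- ifelse(denom > 0, (nMeth + alpha - 1) / denom, 0.5)
  rate <- pmin(1, pmax(0, rate))
  se <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
  rate[nTotal == 0L] <- NA_real_
  se[nTotal == 0L] <- NA_real_
  data.frame(rate = rate, se = se, n_total = nTotal)
}

#' Merge symmetric CpG strand pairs
#'
#' Combines a plus-strand CpG call at position p with the minus-strand call
#' of the same CpG at p+1 by summing read counts (kept on the plus-strand
#' coordinate). Calls without a covered partner are passed through
#' unchanged. Only meaningful for the CpG channel; off by default in
#' quantification.
#'
#' @param sites GRanges of CpG-channel site calls.
#' @return GRanges with merged counts.
#' @export
mergeSymmetricCpG <- function(sites) {
  if (!length(sites)) return(sites)
  str <- as.character(strand(sites))
  key <- paste0(seqnames(sites), ":",
                ifelse(str == "+", start(sites), start(sites) - 1L))
  plus <- which(str == "+")
  minus <- which(str == "-")
  m <- match(key[minus], key[plus])
  paired <- !is.na(m)
  out <- sites[plus]
  out$n_meth[m[paired]] <- out$n_meth[m[paired]] + sites$n_meth[minus[paired]]
  out$n_unmeth[m[paired]] <- out$n_unmeth[m[paired]] +
    sites$n_unmeth[minus[paired]]
  c(out, sites[minus[!paired]])
}

.featureRateOneCell <- function(sites, features, prior) {
  tot <- sites$n_meth + sites$n_unmeth
  sites <- sites[tot >= 1L]
  nf <- length(features)
  if (!length(sites))
    return(list(rate = rep(NA_real_, nf), se = rep(NA_real_, nf),
                nSites = rep(0L, nf)))
  sr <- siteRate(sites$n_meth, sites$n_meth + sites$n_unmeth,
                 prior[1L], prior[2L])
  hits <- findOverlaps(features, sites)
  rate <- rep(NA_real_, nf)
  se <- rep(NA_real_, nf)
  nSites <- rep(0L, nf)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    prec <- 1 / sr$se[sh]^2
    sumPrec <- tapply(prec, qh, sum)
    sumPR <- tapply(prec * sr$rate[sh], qh, sum)
    idx <- as.integer(names(sumPrec))
    rate[idx] <- as.numeric(sumPR / sumPrec)
    se[idx] <- sqrt(1 / as.numeric(sumPrec))
    cnt <- tapply(sh, qh, length)
    nSites[idx] <- as.integer(cnt)
  }
  list(rate = rate, se = se, nSites = nSites)
}

#' Quantify per-feature rates across cells
#'
#' For each cell, site-level MAP rates (beta-binomial shrinkage, prior
#' estimated per cell unless "flat") are aggregated over each genomic
#' feature by inverse-variance weighting: the feature rate is the
#' precision-weighted mean of its site rates and its standard error is
#' \code{sqrt(1/sum(1/se_i^2))}. Features with no covered site in a cell
#' are missing for that cell. Overlap uses 1-based inclusive intervals with
#' inclusive boundaries.
#'
#' @param cellSites named list of site-call GRanges, one per cell
#'   (already partitioned to a single channel).
#' @param features GRanges with \code{feature_id} (and optionally
#'   \code{context_class}, \code{gene_id}) metadata.
#' @param layer "met" or "acc".
#' @param prior "mom" (per-cell method-of-moments) or "flat".
#' @param minSites mask feature/cell entries with fewer covered sites.
#' @param mergeStrands merge symmetric CpG strand pairs before rates.
#' @return A \linkS4class{RateMatrix}.
#' @export
quantifyFeatures <- function(cellSites, features, layer = c("met", "acc"),
                             prior = c("mom", "flat"), minSites = 1L,
                             mergeStrands = FALSE) {
  layer <- match.arg(layer)
  prior <- match.arg(prior)
  stopifnot(!is.null(names(cellSites)), !is.null(features$feature_id))
  nf <- length(features)
  nc <- length(cellSites)
  rate <- matrix(NA_real_, nf, nc,
                 dimnames = list(features$feature_id, names(cellSites)))
  se <- rate
  nSites <- matrix(0L, nf, nc, dimnames = dimnames(rate))
  for (j in seq_len(nc)) {
    s <- cellSites[[j]]
    if (mergeStrands) s <- mergeSymmetricCpG(s)
    tot <- s$n_meth + s$n_unmeth
    pr <- if (prior == "flat") c(1, 1) else
      suppressWarnings(estimateBetaPrior(s$n_meth[tot >= 1],
                                         tot[tot >= 1]))
    res <- .featureRateOneCell(s, features, pr)
    rate[, j] <- res$rate
    se[, j] <- res$se
    nSites[, j] <- res$nSites
  }
  low <- nSites < minSites
  rate[low] <- NA_real_
  se[low] <- NA_real_
  nSites[low] <- 0L
  se2 <- SummarizedExperiment(
    assays = list(rate = rate, se = se, nSites = nSites),
    rowRanges = features
  )
  metadata(se2)$layer <- layer
  new("RateMatrix", se2)
}

#' @rdname rateValues
#' @export
rateValues <- function(x) assay(x, "rate")

#' Accessors for RateMatrix assays
#'
#' @param x a \linkS4class{RateMatrix}.
#' @return Matrix of rates, standard errors, or site counts.
#' @name rateValues
#' @export
seValues <- function(x) assay(x, "se")

#' @rdname rateValues
#' @export
siteCounts <- function(x) assay(x, "nSites")

#' @rdname rateValues
#' @export
layerType <- function(x) metadata(x)$layer

#' Aggregate feature rates across cells
#'
#' Random-effects summary per feature: cells are combined with a normal
#' model in which each cell's feature rate has its own standard error and
#' cells additionally scatter with between-cell variance tau^2 estimated by
#' the method of moments (DerSimonian-Laird). The reported mean uses
#' weights 1/(se^2 + tau^2); the reported sd is tau, the between-cell
#' standard deviation. Features observed in fewer than 2 cells report a
#' mean only (sd NA, flagged).
#'
#' @param x a \linkS4class{RateMatrix}.
#' @return DataFrame with columns mean, sd, n_cells, sd_defined.
#' @export
aggregateAcrossCells <- function(x) {
  r <- rateValues(x)
  s <- seValues(x)
  n <- nrow(r)
  out <- data.frame(mean = rep(NA_real_, n), sd = rep(NA_real_, n),
                    n_cells = integer(n), sd_defined = logical(n),
                    row.names = rownames(r))
  for (i in seq_len(n)) {
    ok <- which(!is.na(r[i, ]))
    k <- length(ok)
    out$n_cells[i] <- k
    if (k == 0L) next
    y <- r[i, ok]
    v <- s[i, ok]^2
    if (k == 1L) {
      out$mean[i] <- y
      next
    }
    w <- 1 / v
    yw <- sum(w * y) / sum(w)
    Q <- sum(w * (y - yw)^2)
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    w2 <- 1 / (v + tau2)
    out$mean[i] <- sum(w2 * y) / sum(w2)
    out$sd[i] <- sqrt(tau2)
    out$sd_defined[i] <- TRUE
  }
  out
}

#' Size-factor normalise and log-transform expression counts
#'
#' Median-of-ratios size factors (ratios of each cell's counts to the
#' per-gene geometric mean over genes detected in all cells), with a
#' library-size fallback for cells in which no such gene is detected.
#' Factors are rescaled to mean 1, counts are divided by the factor and
#' log2(x + 1) transformed.
#'
#' @param counts non-negative integer matrix, genes x cells.
#' @return List with \code{logcounts} (matrix) and \code{sizeFactors}.
#' @export
normalizeExpression <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("all-zero cell(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  if (ncol(counts) == 1L) {
    sf <- 1
  } else {
    allPos <- rowSums(counts > 0) == ncol(counts)
    sf <- rep(NA_real_, ncol(counts))
    if (sum(allPos) >= 1L) {
      ref <- exp(rowMeans(log(counts[allPos, , drop = FALSE])))
      sf <- apply(counts[allPos, , drop = FALSE], 2,
                  function(k) median(k / ref))
    }
    bad <- !is.finite(sf) | sf <= 0
    if (any(bad)) {
      ls <- colSums(counts)
      sf[bad] <- ls[bad] / mean(ls)
    }
    sf <- sf / mean(sf)
  }
  logcounts <- log2(sweep(counts, 2, sf, "/") + 1)
  list(logcounts = logcounts, sizeFactors = sf)
}
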