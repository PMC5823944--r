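#' Rank genes by biological overdispersion
#'
#' Fits a mean-variance trend (rolling median of per-gene variance against
#' mean of the log-normalised counts) and ranks genes by their positive
#' residual above the trend; constant genes are never selected.
#'
#' @param logCounts log-normalised expression, genes x cells.
#' @param nTop number of genes to return (default 500).
#' @param span width of the rolling-median window, as a fraction of genes.
#' @return Character vector of gene ids, most overdispersed first.
#' @export
overdispersedGenes <- function(logCounts, nTop = 500L, span = 0.2) {
  mu <- rowMeans(logCounts)
  v <- apply(logCounts, 1, var)
  ok <- v > 0
  if (!any(ok)) stop("no gene with nonzero variance")
  ord <- order(mu[ok])
  vo <- v[ok][ord]
  k <- max(5L, ceiling(span * sum(ok)))
  half <- k %/% 2L
  n <- length(vo)
  trend <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    median(vo[lo:hi])
  }, numeric(1))
  resid <- vo - trend
  genes <- rownames(logCounts)[ok][ord]
  sel <- genes[order(resid, decreasing = TRUE)]
  if (length(sel) < nTop) {
    warning("only ", length(sel), " informative genes available")
    return(sel)
  }
  sel[seq_len(nTop)]
}

#' Diffusion-map pseudotime from expression
#'
#' Builds a Gaussian-kernel transition matrix over cells with locally
#' scaled bandwidths (each cell's scale is its distance to the k-th
#' nearest neighbour), applies density normalisation, and takes the first
#' nontrivial eigenvector (diffusion component 1). Pseudotime is the
#' min-max-scaled rank of cells along DC1, oriented so a user-named marker
#' gene changes in the stated direction.
#'
#' @param logCounts log-normalised expression, genes x cells.
#' @param genes genes to use (e.g. from \code{\link{overdispersedGenes}}).
#' @param marker orientation marker gene id.
#' @param orientation "decreasing" (default) or "increasing": expected
#'   behaviour of the marker along pseudotime.
#' @param k neighbour index for the local bandwidth (default 5).
#' @param nComponents diffusion components to retain.
#' @return A \linkS4class{PseudotimeResult}.
#' @export
diffusionPseudotime <- function(logCounts, genes = rownames(logCounts),
                                marker, orientation = c("decreasing",
                                                        "increasing"),
                                k = 5L, nComponents = 10L) {
  orientation <- match.arg(orientation)
  genes <- intersect(genes, rownames(logCounts))
  X <- t(logCounts[genes, , drop = FALSE])
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 cells")
  D <- as.matrix(dist(X))
  sig <- apply(D, 1, function(d) sort(d)[k + 1L])
  sig[sig <= 0] <- min(sig[sig > 0])
  K <- exp(-D^2 / outer(sig, sig))
  diag(K) <- 0
  if (any(rowSums(K) < 1e-12))
    stop("kernel graph is disconnected; increase the bandwidth (k)")
  ## density normalisation (alpha = 1), then symmetric normalisation
  q <- rowSums(K)
  K <- K / outer(q, q)
  dg <- rowSums(K)
  S <- K / outer(sqrt(dg), sqrt(dg))
  eig <- eigen(S, symmetric = TRUE)
  nComponents <- min(nComponents, n - 1L)
  comps <- eig$vectors[, seq(2L, nComponents + 1L), drop = FALSE] /
    sqrt(dg)
  rownames(comps) <- rownames(X)
  dc1 <- comps[, 1L]
  tau <- (rank(dc1, ties.method = "average") - 1) / (n - 1)
  if (!marker %in% rownames(logCounts))
    stop("marker gene '", marker, "' not found")
  mexp <- logCounts[marker, rownames(X)]
  rho <- suppressWarnings(cor(tau, mexp, method = "spearman"))
  flip <- if (orientation == "decreasing") !is.na(rho) && rho > 0
          else !is.na(rho) && rho < 0
  if (flip) tau <- 1 - tau
  new("PseudotimeResult", tau = setNames(tau, rownames(X)),
      components = comps, genes = genes, marker = marker,
      orientation = orientation)
}

#' @rdname pseudotimeTau
#' @export
pseudotimeTau <- function(x) x@tau

#' Accessors for pseudotime results
#'
#' @param x a \linkS4class{PseudotimeResult}.
#' @return Named pseudotime vector or diffusion-component matrix.
#' @name pseudotimeTau
#' @export
diffusionComponents <- function(x) x@components

#' Test accessibility-profile dynamics along pseudotime
#'
#' For each gene, the per-cell fitted profiles are projected onto their
#' first principal axis; the projection is computed in curve space (the
#' weight vectors mapped through the basis onto a position grid), which is
#' the same linear functional of the weights but immune to the
#' ill-conditioned directions of correlated basis functions. The test
#' statistic is the Spearman correlation of the projection with
#' pseudotime, with a permutation p-value (pseudotime permuted
#' \code{nPerm} times under a fixed seed) and BH adjustment across genes.
#'
#' @param fitSets list of \linkS4class{ProfileFitSet} (one per gene).
#' @param pt a \linkS4class{PseudotimeResult} or named pseudotime vector.
#' @param nPerm permutations (0 returns statistics without p-values).
#' @param minCells minimum fitted cells per gene.
#' @param fdr significance level.
#' @param seed RNG seed for the permutations.
#' @return data.frame per gene: gene_id, statistic, p, q, sig, n.
#' @export
profileTrajectoryAssociation <- function(fitSets, pt, nPerm = 1000L,
                                         minCells = 20L, fdr = 0.1,
                                         seed = 1L) {
  tau <- if (is(pt, "PseudotimeResult")) pseudotimeTau(pt) else pt
  grid <- seq(-1, 1, length.out = 25L)
  rows <- lapply(fitSets, function(fs) {
    cells <- intersect(fs@cellIds, names(tau))
    if (length(cells) < minCells) return(NULL)
    W <- profileWeights(fs)[cells, , drop = FALSE]
    curves <- t(apply(W, 1, profileCurve, basis = profileBasis(fs),
                      x = grid))
    Cc <- scale(curves, center = TRUE, scale = FALSE)
    if (all(abs(Cc) < 1e-12)) return(NULL)
    pc <- prcomp(Cc, center = FALSE)
    if (pc$sdev[1L] < 1e-10) return(NULL)
    proj <- pc$x[, 1L]
    tt <- tau[cells]
    stat <- suppressWarnings(cor(proj, tt, method = "spearman"))
    if (is.na(stat)) return(NULL)
    p <- NA_real_
    if (nPerm > 0L) {
      set.seed(seed)
      exceed <- 0L
      for (b in seq_len(nPerm)) {
        rs <- suppressWarnings(cor(proj, sample(tt), method = "spearman"))
        if (!is.na(rs) && abs(rs) >= abs(stat)) exceed <- exceed + 1L
      }
      p <- (1 + exceed) / (nPerm + 1)
    }
    data.frame(gene_id = fs@geneId, statistic = stat, p = p,
               n = length(cells), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene_id = character(), statistic = numeric(),
                      p = numeric(), q = numeric(), sig = logical(),
                      n = integer()))
  out$q <- if (all(is.na(out$p))) NA_real_ else bhAdjust(out$p)
  out$sig <- !is.na(out$q) & out$q < fdr
  rownames(out) <- NULL
  out
}

#' Trend of methylation-accessibility coupling along pseudotime
#'
#' Per genomic context, the Pearson correlation between each cell's
#' methylation-accessibility correlation coefficient and its pseudotime,
#' with a two-tailed t-test. A negative trend statistic means coupling
#' strengthens (the per-cell correlation becomes more negative) along the
#' trajectory.
#'
#' @param perCell data.frame from
#'   \code{\link{acrossGenesScan}$perCell} (columns cell_id, context, r).
#' @param pt a \linkS4class{PseudotimeResult} or named pseudotime vector.
#' @param minCells minimum cells per context (default 10).
#' @return data.frame per context: context, trend, p, q, n.
#' @export
couplingVsPseudotime <- function(perCell, pt, minCells = 10L) {
  tau <- if (is(pt, "PseudotimeResult")) pseudotimeTau(pt) else pt
  rows <- lapply(unique(perCell$context), function(g) {
    sub <- perCell[perCell$context == g, ]
    sub <- sub[sub$cell_id %in% names(tau), ]
    if (nrow(sub) < minCells) return(NULL)
    tt <- tau[sub$cell_id]
    if (sd(sub$r) == 0 || sd(tt) == 0) {
      return(data.frame(context = g, trend = 0, p = 1, n = nrow(sub),
                        stringsAsFactors = FALSE))
    }
    ct <- cor.test(sub$r, tt)
    data.frame(context = g, trend = unname(ct$estimate), p = ct$p.value,
               n = nrow(sub), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(context = character(), trend = numeric(),
                      p = numeric(), q = numeric(), n = integer()))
  out$q <- bhAdjust(out$p)
  rownames(out) <- NULL
  out
}

#' @importFrom stats dist
NULL
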