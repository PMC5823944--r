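#' Weighted Pearson correlation
#'
#' Pearson correlation with per-observation weights entering every moment:
#' \code{r = sum(w (x - mx)(y - my)) / sqrt(sum(w (x - mx)^2) sum(w (y - my)^2))}
#' with weighted means mx, my. Weights are rescaled internally to sum to
#' the number of observations; with equal weights this reduces exactly to
#' the ordinary Pearson correlation. Zero weighted variance in either
#' vector yields NA (undefined, excluded from scans).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param w positive weights (recycled if length 1).
#' @return Correlation in [-1, 1], or NA if undefined.
#' @export
weightedPearson <- function(x, y, w = 1) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L)
  w <- rep_len(w, n)
  stopifnot(all(w > 0))
  w <- w * n / sum(w)
  mx <- sum(w * x) / n
  my <- sum(w * y) / n
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx <= .Machine$double.eps * n || vy <= .Machine$double.eps * n)
    return(NA_real_)
  r <- sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
  min(1, max(-1, r))
}

#' Two-tailed t-test for a (weighted) Pearson correlation
#'
#' \code{t = r sqrt((n - 2)/(1 - r^2))} referred to a Student's t
#' distribution with n - 2 degrees of freedom. The scans pass the Kish
#' effective sample size as n, since unequal coverage weights inflate the
#' null variance of the weighted correlation. |r| = 1 returns an infinite
#' t and p = 0.
#'
#' @param r correlation(s).
#' @param n number(s) of observations, >= 3.
#' @return data.frame with columns t and p.
#' @export
pearsonTTest <- function(r, n) {
  if (any(n < 3L)) stop("n must be >= 3")
  stopifnot(all(abs(r) <= 1 + 1e-12, na.rm = TRUE))
  r <- pmin(1, pmax(-1, r))
  t <- ifelse(abs(r) >= 1, sign(r) * Inf,
              r * sqrt((n - 2) / (1 - r^2)))
  p <- ifelse(is.infinite(t), 0, 2 * pt(-abs(t), df = n - 2))
  data.frame(t = t, p = p)
}

#' Benjamini-Hochberg adjustment, optionally within groups
#'
#' Step-up adjusted q-values capped at 1; when a grouping key is supplied
#' (e.g. genomic context), the adjustment is applied separately within each
#' group. NA p-values are excluded and returned as NA.
#'
#' @param p p-values in [0, 1].
#' @param group optional grouping vector of the same length.
#' @return q-values.
#' @export
bhAdjust <- function(p, group = NULL) {
  if (is.null(group)) return(p.adjust(p, method = "BH"))
  stopifnot(length(group) == length(p))
  q <- rep(NA_real_, length(p))
  for (g in unique(group)) {
    sel <- which(group == g)
    q[sel] <- p.adjust(p[sel], method = "BH")
  }
  q
}

#' Associate genomic features with their closest gene
#'
#' A feature is assigned to the nearest gene whose body, extended by
#' \code{window} bp on both sides, contains the feature midpoint;
#' unassociated features get NA.
#'
#' @param features GRanges with \code{feature_id}.
#' @param genes GRanges with \code{gene_id}.
#' @param window extension in bp (default 10000, the across-cells scan
#'   rule; pseudo-bulk stratification uses 5000).
#' @return \code{features} with a \code{gene_id} metadata column.
#' @export
associateGenes <- function(features, genes, window = 10000L) {
  mid <- GRanges(seqnames(features),
                 IRanges((start(features) + end(features)) %/% 2L, width = 1L))
  ext <- genes
  start(ext) <- pmax(1L, start(genes) - window)
  end(ext) <- end(genes) + window
  hits <- findOverlaps(mid, ext, ignore.strand = TRUE)
  gid <- rep(NA_character_, length(features))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    d <- GenomicRanges::distance(mid[qh], genes[sh], ignore.strand = TRUE)
    ord <- order(qh, d)
    first <- !duplicated(qh[ord])
    gid[qh[ord][first]] <- genes$gene_id[sh[ord][first]]
  }
  features$gene_id <- gid
  features
}

#' Promoter windows around transcription start sites
#'
#' The accessibility layer uses a narrow window (+/- 50 bp) centred on the
#' TSS to focus on the nucleosome-depleted region; the methylation layer
#' uses a wider +/- 2 kb window. Single-cell profile fitting uses +/- 200
#' bp.
#'
#' @param genes GRanges with \code{gene_id}; the TSS is the 5' end of each
#'   gene on its strand.
#' @param layer "acc", "met" or "profile".
#' @param flank optional explicit half-width in bp (overrides the layer
#'   default).
#' @return GRanges of promoter windows with feature_id, context_class and
#'   gene_id.
#' @export
promoterWindows <- function(genes, layer = c("acc", "met", "profile"),
                            flank = NULL) {
  layer <- match.arg(layer)
  if (is.null(flank))
    flank <- c(acc = 50L, met = 2000L, profile = 200L)[[layer]]
  str <- as.character(strand(genes))
  tss <- ifelse(str == "-", end(genes), start(genes))
  gr <- GRanges(seqnames(genes),
                IRanges(pmax(1L, tss - flank), tss + flank),
                strand = str,
                feature_id = paste0(genes$gene_id, "_prom"),
                context_class = "promoter",
                gene_id = genes$gene_id)
  gr
}

#' Parameters of the correlation scans
#'
#' @param minSites minimum covered sites per feature per cell (entries
#'   below are treated as missing).
#' @param minCells minimum jointly observed cells per locus.
#' @param varQuantile fraction of most variable loci kept per context.
#' @param fdr significance level on BH-adjusted q-values.
#' @param minLoci minimum qualifying loci for a per-cell correlation.
#' @param exprVarFilter drop genes below the median expression variance
#'   before expression scans.
#' @return Named list of parameters.
#' @export
scanParams <- function(minSites = 3L, minCells = 20L, varQuantile = 0.5,
                       fdr = 0.1, minLoci = 5L, exprVarFilter = TRUE) {
  list(minSites = minSites, minCells = minCells, varQuantile = varQuantile,
       fdr = fdr, minLoci = minLoci, exprVarFilter = exprVarFilter)
}

## Internal: align layer B values/weights per feature of x.
## Returns list(valsB: features x cells matrix, weights: matrix)
.alignLayers <- function(x, y, params) {
  rx <- rateValues(x)
  nx <- siteCounts(x)
  nx[nx < params$minSites] <- 0L
  rx[nx == 0L] <- NA_real_
  if (is(y, "RateMatrix")) {
    common <- intersect(colnames(x), colnames(y))
    if (!length(common)) stop("cell sets of the two layers are disjoint")
    ry <- rateValues(y)[, common, drop = FALSE]
    ny <- siteCounts(y)[, common, drop = FALSE]
    ny[ny < params$minSites] <- 0L
    ry[ny == 0L] <- NA_real_
    feats <- intersect(rownames(rx), rownames(ry))
    rx <- rx[feats, common, drop = FALSE]
    nx <- nx[feats, common, drop = FALSE]
    ry <- ry[feats, , drop = FALSE]
    ny <- ny[feats, , drop = FALSE]
    ## coverage weight: CpG (methylation) coverage whenever methylation
    ## participates, else the epigenetic coverage of x
    w <- if (identical(layerType(x), "met")) nx
         else if (identical(layerType(y), "met")) ny
         else nx
    keepRanges <- rowRanges(x)[match(feats, rownames(rateValues(x)))]
    list(x = rx, y = ry, w = w, features = keepRanges, pair = "epi-epi")
  } else {
    expr <- if (is.list(y)) y$logcounts else y
    common <- intersect(colnames(rx), colnames(expr))
    if (!length(common)) stop("cell sets of the two layers are disjoint")
    feats <- rowRanges(x)
    gid <- feats$gene_id
    keep <- !is.na(gid) & gid %in% rownames(expr)
    if (params$exprVarFilter && nrow(expr) > 1L) {
      gv <- apply(expr, 1, var)
      keepGenes <- rownames(expr)[gv >= median(gv)]
      keep <- keep & gid %in% keepGenes
    }
    rx <- rx[keep, common, drop = FALSE]
    nx <- nx[keep, common, drop = FALSE]
    ey <- expr[gid[keep], common, drop = FALSE]
    rownames(ey) <- rownames(rx)
    list(x = rx, y = ey, w = nx, features = feats[keep], pair = "epi-expr")
  }
}

#' Per-locus association scan across cells
#'
#' One weighted-correlation test per locus between two molecular layers,
#' with the filters of the study design: feature/cell entries with fewer
#' than \code{minSites} covered sites are missing; only loci observed in at
#' least \code{minCells} cells in both layers are tested; only the top
#' \code{varQuantile} most variable loci per genomic context are kept
#' (ties at the cut retained); for expression pairs, genes below the median
#' expression variance are dropped first (independent filtering). Weights
#' are the CpG coverage whenever methylation participates, otherwise the
#' GpC coverage, rescaled to mean 1 per locus. P-values come from a
#' two-tailed t-test and are BH-adjusted within each context; significance
#' is called at \code{q < fdr}.
#'
#' @param x a \linkS4class{RateMatrix} (methylation or accessibility).
#' @param y a second \linkS4class{RateMatrix}, or a log-normalised
#'   expression matrix (genes x cells; features of \code{x} must then carry
#'   \code{gene_id}).
#' @param params see \code{\link{scanParams}}.
#' @return data.frame, one row per tested locus: feature_id, context,
#'   gene_id, r, t, p, q, n, mean_weight, sig.
#' @export
acrossCellsScan <- function(x, y, params = scanParams()) {
  al <- .alignLayers(x, y, params)
  ctx <- al$features$context_class %||% rep("all", nrow(al$x))
  ## top variable loci per context (variance of layer-x rates across cells)
  keep <- logical(nrow(al$x))
  v <- apply(al$x, 1, function(z) if (sum(!is.na(z)) >= 2) var(z, na.rm = TRUE)
             else NA_real_)
  for (g in unique(ctx)) {
    sel <- which(ctx == g & !is.na(v))
    if (!length(sel)) next
    cut <- quantile(v[sel], probs = 1 - params$varQuantile, type = 1)
    keep[sel[v[sel] >= cut]] <- TRUE
  }
  idx <- which(keep)
  res <- lapply(idx, function(i) {
    ok <- which(!is.na(al$x[i, ]) & !is.na(al$y[i, ]))
    if (length(ok) < params$minCells) return(NULL)
    w <- al$w[i, ok]
    w <- w / mean(w)
    r <- weightedPearson(al$x[i, ok], al$y[i, ok], w)
    if (is.na(r)) return(NULL)
    ## df from the Kish effective sample size: unequal coverage weights
    ## inflate the null variance of r, so the raw cell count would be
    ## anti-conservative
    nEff <- sum(w)^2 / sum(w^2)
    tt <- pearsonTTest(r, max(3, nEff))
    data.frame(feature_id = rownames(al$x)[i], context = ctx[i],
               gene_id = al$features$gene_id[i] %||% NA_character_,
               r = r, t = tt$t, p = tt$p, n = length(ok),
               mean_weight = mean(al$w[i, ok]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    warning("no locus passed the scan filters")
    return(data.frame(feature_id = character(), context = character(),
                      gene_id = character(), r = numeric(), t = numeric(),
                      p = numeric(), q = numeric(), n = integer(),
                      mean_weight = numeric(), sig = logical()))
  }
  res$q <- bhAdjust(res$p, res$context)
  res$sig <- res$q < params$fdr
  rownames(res) <- NULL
  res
}

#' Per-cell association scan across loci
#'
#' For each cell, the weighted Pearson correlation between two layers
#' across all qualifying loci of each genomic context (one association test
#' per cell), plus the pseudo-bulk correlation computed on the cell-mean
#' matrices with cell-mean weights.
#'
#' @param x,y as in \code{\link{acrossCellsScan}}.
#' @param params see \code{\link{scanParams}}.
#' @return List with \code{perCell} (cell_id, context, r, t, p, n) and
#'   \code{pseudobulk} (context, r, n).
#' @export
acrossGenesScan <- function(x, y, params = scanParams()) {
  al <- .alignLayers(x, y, params)
  ctx <- al$features$context_class %||% rep("all", nrow(al$x))
  cells <- colnames(al$x)
  perCell <- list()
  pseudo <- list()
  nSkipped <- 0L
  for (g in unique(ctx)) {
    rows <- which(ctx == g)
    for (j in seq_along(cells)) {
      ok <- rows[!is.na(al$x[rows, j]) & !is.na(al$y[rows, j])]
      if (length(ok) < max(3L, params$minLoci)) {
        nSkipped <- nSkipped + 1L
        next
      }
      w <- al$w[ok, j]
      w <- w / mean(w)
      r <- weightedPearson(al$x[ok, j], al$y[ok, j], w)
      if (is.na(r)) next
      nEff <- sum(w)^2 / sum(w^2)
      tt <- pearsonTTest(r, max(3, nEff))
      perCell[[length(perCell) + 1L]] <-
        data.frame(cell_id = cells[j], context = g, r = r, t = tt$t,
                   p = tt$p, n = length(ok), stringsAsFactors = FALSE)
    }
    mx <- rowMeans(al$x[rows, , drop = FALSE], na.rm = TRUE)
    my <- rowMeans(al$y[rows, , drop = FALSE], na.rm = TRUE)
    mw <- rowMeans(al$w[rows, , drop = FALSE], na.rm = TRUE)
    ok <- which(is.finite(mx) & is.finite(my) & mw > 0)
    if (length(ok) >= 3L) {
      r <- weightedPearson(mx[ok], my[ok], mw[ok] / mean(mw[ok]))
      pseudo[[length(pseudo) + 1L]] <-
        data.frame(context = g, r = r, n = length(ok),
                   stringsAsFactors = FALSE)
    }
  }
  if (nSkipped > 0L)
    warning(nSkipped, " cell/context combination(s) omitted: fewer than ",
            params$minLoci, " qualifying loci")
  list(perCell = do.call(rbind, perCell) %||%
         data.frame(cell_id = character(), context = character(),
                    r = numeric(), t = numeric(), p = numeric(),
                    n = integer()),
       pseudobulk = do.call(rbind, pseudo) %||%
         data.frame(context = character(), r = numeric(), n = integer()))
}
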