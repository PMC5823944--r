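#' Pseudo-bulk running-window profile over a region
#'
#' Per cell, site-level rates are averaged within running windows (default
#' 50 bp) along the region; the per-window mean and standard deviation
#' across cells and the number of contributing cells are reported. Windows
#' covered in no cell are missing.
#'
#' @param cellRates named list (one per cell) of site-call GRanges with a
#'   \code{rate} metadata column (e.g. from \code{\link{siteRate}}).
#' @param region GRanges of length 1.
#' @param window window size in bp.
#' @param step step size in bp.
#' @return data.frame with columns start, center, mean, sd, n_cells
#'   (coordinates relative to the region start, 1-based).
#' @export
pseudobulkProfile <- function(cellRates, region, window = 50L, step = 25L) {
  stopifnot(length(region) == 1L)
  len <- width(region)
  if (window > len) stop("window larger than the region")
  starts <- seq(1L, len - window + 1L, by = step)
  nW <- length(starts)
  perCell <- matrix(NA_real_, length(cellRates), nW)
  for (i in seq_along(cellRates)) {
    s <- cellRates[[i]]
    s <- s[as.character(seqnames(s)) == as.character(seqnames(region)) &
             start(s) >= start(region) & start(s) <= end(region)]
    if (!length(s)) next
    rel <- start(s) - start(region) + 1L
    rate <- s$rate
    for (j in seq_len(nW)) {
      inw <- rel >= starts[j] & rel < starts[j] + window
      if (any(inw)) perCell[i, j] <- mean(rate[inw])
    }
  }
  nCells <- colSums(!is.na(perCell))
  mu <- ifelse(nCells > 0, colMeans(perCell, na.rm = TRUE), NA_real_)
  sdv <- apply(perCell, 2, function(z) {
    z <- z[!is.na(z)]
    if (length(z) >= 2) sd(z) else if (length(z) == 1) 0 else NA_real_
  })
  data.frame(start = starts, center = starts + (window - 1) / 2,
             mean = mu, sd = sdv, n_cells = nCells)
}

#' Locate peaks in a pseudo-bulk profile
#'
#' Lightly smooths the mean profile (running mean of 3 windows) and
#' reports local maxima exceeding the profile median; used to measure
#' nucleosome-linker periodicity.
#'
#' @param profile data.frame from \code{\link{pseudobulkProfile}}.
#' @return Numeric vector of peak centre positions (region-relative bp).
#' @export
profilePeaks <- function(profile) {
  y <- profile$mean
  ok <- !is.na(y)
  y[!ok] <- median(y, na.rm = TRUE)
  k <- length(y)
  if (k < 3L) return(numeric(0))
  ys <- c(y[1L], (y[-c(1L, k)] + y[-c(k - 1L, k)] + y[-c(1L, 2L)]) / 3,
          y[k])
  isPeak <- c(FALSE, ys[-c(1L, k)] > ys[-c(k - 1L, k)] &
                ys[-c(1L, k)] >= ys[-c(1L, 2L)], FALSE) &
    ys > median(ys)
  profile$center[isPeak]
}

#' Stratify genes by mean log-normalised expression
#'
#' Low: x < 2; Medium: 2 <= x <= 6; High: x > 6.
#'
#' @param x mean log2-normalised expression per gene.
#' @return factor with levels Low, Medium, High.
#' @export
stratifyGenesByExpression <- function(x) {
  factor(ifelse(x < 2, "Low", ifelse(x > 6, "High", "Medium")),
         levels = c("Low", "Medium", "High"))
}

#' Select genes eligible for single-cell profile fitting
#'
#' A gene is kept iff at least \code{minCellFrac} of the cells have at
#' least \code{minSites} covered GpC sites within its TSS window (both
#' boundaries inclusive).
#'
#' @param cellSites named list of GpC-channel site-call GRanges.
#' @param tssWindows GRanges with \code{gene_id} (e.g.
#'   \code{promoterWindows(genes, "profile")}).
#' @param minCellFrac minimum fraction of cells (default 0.4).
#' @param minSites minimum covered sites per cell (default 10).
#' @return Character vector of gene ids.
#' @export
selectProfiledGenes <- function(cellSites, tssWindows, minCellFrac = 0.4,
                                minSites = 10L) {
  nc <- length(cellSites)
  counts <- matrix(0L, length(tssWindows), nc)
  for (j in seq_len(nc)) {
    s <- cellSites[[j]]
    s <- s[(s$n_meth + s$n_unmeth) >= 1L]
    if (!length(s)) next
    counts[, j] <- GenomicRanges::countOverlaps(tssWindows, s,
                                                ignore.strand = TRUE)
  }
  frac <- rowMeans(counts >= minSites)
  keep <- frac >= minCellFrac
  if (!any(keep)) warning("no gene passes the profiling coverage filter")
  tssWindows$gene_id[keep]
}

#' Accessibility-heterogeneity report per cluster number
#'
#' Groups genes by the number of accessibility clusters chosen by
#' \code{\link{clusterProfiles}} and summarises the expression distribution
#' per group; when a promoter mark annotation is supplied, the proportion
#' of promoters per mark class is added.
#'
#' @param mixtures list of \linkS4class{MixtureResult}.
#' @param meanExpr named numeric, mean log-normalised expression per gene.
#' @param marks optional named character, promoter mark class per gene
#'   (e.g. "H3K4me3", "bivalent").
#' @return data.frame, one row per observed K.
#' @export
heterogeneityReport <- function(mixtures, meanExpr, marks = NULL) {
  ks <- vapply(mixtures, clusterK, integer(1))
  genes <- vapply(mixtures, function(m) m@geneId, character(1))
  expr <- meanExpr[genes]
  out <- do.call(rbind, lapply(sort(unique(ks)), function(k) {
    sel <- ks == k
    data.frame(K = k, n_genes = sum(sel),
               median_expr = median(expr[sel], na.rm = TRUE),
               q1_expr = quantile(expr[sel], 0.25, na.rm = TRUE,
                                  names = FALSE),
               q3_expr = quantile(expr[sel], 0.75, na.rm = TRUE,
                                  names = FALSE))
  }))
  if (!is.null(marks)) {
    classes <- sort(unique(marks))
    for (cl in classes) {
      out[[paste0("prop_", cl)]] <- vapply(out$K, function(k) {
        g <- genes[ks == k]
        mean(marks[g] == cl, na.rm = TRUE)
      }, numeric(1))
    }
  }
  rownames(out) <- NULL
  out
}

#' Predict expression from per-gene epigenetic features, per cell
#'
#' For each cell, a linear regression across genes of expression on that
#' cell's per-gene features (a scalar accessibility rate, or the fitted
#' profile basis weights). Reports the in-sample adjusted R-squared (which
#' accounts for the differing feature counts of the two modes) and the
#' K-fold cross-validated Pearson correlation between observed and
#' predicted expression.
#'
#' @param featureList named list, one entry per cell: a genes x p numeric
#'   matrix (rownames are gene ids; rows with NA are dropped).
#' @param expr log-normalised expression matrix, genes x cells.
#' @param folds number of CV folds.
#' @param seed RNG seed for the fold split.
#' @return data.frame per cell: cell_id, r_cv, adj_r2, n_genes.
#' @export
predictExpression <- function(featureList, expr, folds = 10L, seed = 1L) {
  cells <- intersect(names(featureList), colnames(expr))
  out <- lapply(cells, function(cell) {
    X <- featureList[[cell]]
    if (is.null(dim(X))) X <- matrix(X, ncol = 1L,
                                     dimnames = list(names(X), NULL))
    genes <- intersect(rownames(X)[rowSums(is.na(X)) == 0L],
                       rownames(expr))
    X <- X[genes, , drop = FALSE]
    y <- expr[genes, cell]
    if (length(genes) <= ncol(X) + 2L)
      stop("fewer genes than features for cell ", cell)
    df <- data.frame(y = y, X)
    fit <- lm(y ~ ., data = df)
    adjR2 <- summary(fit)$adj.r.squared
    set.seed(seed)
    fold <- sample(rep_len(seq_len(folds), length(y)))
    pred <- rep(NA_real_, length(y))
    for (f in unique(fold)) {
      hold <- fold == f
      m <- lm(y ~ ., data = df[!hold, , drop = FALSE])
      pred[hold] <- predict(m, newdata = df[hold, , drop = FALSE])
    }
    rcv <- if (sd(pred) > 0 && sd(y) > 0) cor(y, pred) else NA_real_
    data.frame(cell_id = cell, r_cv = rcv, adj_r2 = adjR2,
               n_genes = length(y), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Gene-set enrichment by Fisher's exact test
#'
#' One 2x2 exact test per gene set (query membership x set membership over
#' the universe); odds ratios are the sample cross-product ratio and
#' p-values are BH-adjusted across sets.
#'
#' @param query character vector of genes (subset of universe).
#' @param universe character vector of all eligible genes.
#' @param geneSets named list of character vectors.
#' @return data.frame per set: set, n_overlap, odds_ratio, p, q.
#' @export
fisherEnrichment <- function(query, universe, geneSets) {
  if (!length(query)) stop("empty query")
  stopifnot(all(query %in% universe))
  out <- do.call(rbind, lapply(names(geneSets), function(nm) {
    set <- intersect(geneSets[[nm]], universe)
    a <- length(intersect(query, set))
    b <- length(setdiff(query, set))
    cc <- length(setdiff(set, query))
    d <- length(universe) - a - b - cc
    or <- if (b * cc == 0) {
      if (a * d == 0) NaN else Inf
    } else (a * d) / (b * cc)
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2L))$p.value
    data.frame(set = nm, n_overlap = a, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  }))
  out$q <- bhAdjust(out$p)
  rownames(out) <- NULL
  out
}

#' @importFrom stats lm predict
NULL
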