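test_that("weighted Pearson matches the weighted-moment oracle and cor()", {
  expect_equal(weightedPearson(1:3, 1:3), 1)
  expect_equal(weightedPearson(1:3, 3:1), -1)
  expect_equal(weightedPearson(c(0, 1, 2), c(0, 1, 1), c(1, 1, 2)),
               wpOracle(c(0, 1, 2), c(0, 1, 1), c(1, 1, 2)),
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n); w <- rexp(n) + 0.1
    ## equal weights reduce exactly to textbook Pearson
    expect_equal(weightedPearson(x, y, rep(2, n)), cor(x, y),
                 tolerance = 1e-12)
    ## oracle agreement, symmetry, affine invariance
    expect_equal(weightedPearson(x, y, w), wpOracle(x, y, w),
                 tolerance = 1e-12)
    expect_equal(weightedPearson(x, y, w), weightedPearson(y, x, w),
                 tolerance = 1e-12)
    expect_equal(weightedPearson(2 * x + 3, -1 * y + 5, w),
                 -weightedPearson(x, y, w), tolerance = 1e-12)
  }
  ## zero weighted variance is undefined
  expect_true(is.na(weightedPearson(c(1, 1, 1), 1:3)))
})

test_that("the correlation t-test matches the t-distribution", {
  tt <- pearsonTTest(0, 20)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  expect_equal(pearsonTTest(1, 10)$p, 0)
  expect_true(is.infinite(pearsonTTest(1, 10)$t))
  tt2 <- pearsonTTest(0.5, 20)
  expect_equal(tt2$t, 0.5 * sqrt(18 / 0.75), tolerance = 1e-9)
  expect_equal(tt2$p, 2 * pt(-0.5 * sqrt(18 / 0.75), 18),
               tolerance = 1e-12)
  expect_equal(round(tt2$p, 4), 0.0248)
  expect_error(pearsonTTest(0.5, 2), "n must be")
})

test_that("BH adjustment is correct, grouped, order-invariant and capped", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(3)
  p <- runif(50)
  g <- sample(c("a", "b"), 50, TRUE)
  q <- bhAdjust(p, g)
  perm <- sample(50)
  expect_equal(bhAdjust(p[perm], g[perm]), q[perm])
  expect_true(all(q <= 1))
  expect_true(all(q >= p))
  ## groups are adjusted independently
  expect_equal(q[g == "a"], p.adjust(p[g == "a"], "BH"))
  ## NA p-values propagate as NA
  p[3] <- NA
  expect_true(is.na(bhAdjust(p)[3]))
})

test_that("features associate to the nearest gene within the window", {
  genes <- GRanges("chr1", IRanges(c(1000L, 30000L), width = 2000L),
                   strand = "+", gene_id = c("gA", "gB"))
  feats <- GRanges("chr1",
                   IRanges(c(3500L, 13500L, 29000L), width = 200L),
                   feature_id = c("f1", "f2", "f3"),
                   context_class = "enhancer")
  out <- associateGenes(feats, genes, window = 10000L)
  expect_equal(out$gene_id, c("gA", NA, "gB"))
  ## widening the window rescues the middle feature
  out5k <- associateGenes(feats, genes, window = 15000L)
  expect_equal(out5k$gene_id[2], "gA")
})

test_that("promoter windows differ by layer around the TSS", {
  genes <- GRanges("chr1", IRanges(5000L, 7000L), strand = "+",
                   gene_id = "g1")
  acc <- promoterWindows(genes, "acc")
  met <- promoterWindows(genes, "met")
  prof <- promoterWindows(genes, "profile")
  expect_equal(width(acc), 101L)
  expect_equal(width(met), 4001L)
  expect_equal(width(prof), 401L)
  ## a site 500 bp from the TSS enters the methylation window only
  site <- GRanges("chr1", IRanges(5500L, width = 1L), strand = "+",
                  n_meth = 1L, n_unmeth = 0L, context = "CpG",
                  trinucleotide = "ACG")
  expect_equal(GenomicRanges::countOverlaps(acc, site), 0L)
  expect_equal(GenomicRanges::countOverlaps(met, site), 1L)
  ## minus-strand gene anchors at its 3' coordinate end
  genesM <- GRanges("chr1", IRanges(5000L, 7000L), strand = "-",
                    gene_id = "g2")
  accM <- promoterWindows(genesM, "acc")
  expect_equal(start(accM), 6950L)
  expect_equal(end(accM), 7050L)
})

test_that("the locus scan enforces its filters", {
  cfg <- simConfig(nCells = 40, rhoME = 0, rhoAE = 0)
  sim <- simulateFeatureRates(cfg, seed = 17)
  sc <- acrossCellsScan(sim$met, sim$logcounts)
  expect_true(all(sc$n >= 20))
  expect_true(all(sc$q >= sc$p - 1e-12))
  ## a locus observed in fewer than 20 cells is absent
  r <- rateValues(sim$met)
  drop <- which(rowSums(!is.na(r)) >= 20)[1L]
  ns <- SummarizedExperiment::assay(sim$met, "nSites")
  rt <- SummarizedExperiment::assay(sim$met, "rate")
  sse <- SummarizedExperiment::assay(sim$met, "se")
  ns[drop, 21:40] <- 0L
  rt[drop, 21:40] <- NA_real_
  sse[drop, 21:40] <- NA_real_
  SummarizedExperiment::assay(sim$met, "nSites") <- ns
  SummarizedExperiment::assay(sim$met, "rate") <- rt
  SummarizedExperiment::assay(sim$met, "se") <- sse
  sc2 <- acrossCellsScan(sim$met, sim$logcounts)
  expect_false(rownames(r)[drop] %in% sc2$feature_id)
  ## disjoint cell sets error
  exprRenamed <- sim$logcounts
  colnames(exprRenamed) <- paste0("other_", colnames(exprRenamed))
  expect_error(acrossCellsScan(sim$met, exprRenamed), "disjoint")
})

test_that("per-cell scan recovers global coupling and the null is centred", {
  medians <- c()
  for (s in 1:3) {
    cfg <- simConfig(nCells = 40, rhoMA = -0.5, rhoME = 0, rhoAE = 0)
    sim <- simulateFeatureRates(cfg, seed = 100 + s)
    gs <- suppressWarnings(acrossGenesScan(sim$met, sim$acc))
    byCtx <- tapply(gs$perCell$r, gs$perCell$context, median)
    expect_true(all(byCtx < 0))
    medians <- c(medians, median(gs$perCell$r))
  }
  nulls <- c()
  for (s in 1:5) {
    cfg0 <- simConfig(nCells = 40, rhoMA = 0, rhoME = 0, rhoAE = 0)
    sim0 <- simulateFeatureRates(cfg0, seed = 200 + s)
    gs0 <- suppressWarnings(acrossGenesScan(sim0$met, sim0$acc))
    nulls <- c(nulls, median(gs0$perCell$r))
  }
  expect_lt(abs(median(nulls)), 0.05)
})

test_that("pseudo-bulk correlation equals the weighted Pearson of means", {
  cfg <- simConfig(nCells = 40)
  sim <- simulateFeatureRates(cfg, seed = 23)
  gs <- suppressWarnings(acrossGenesScan(sim$met, sim$acc))
  al <- scNOMe:::.alignLayers(sim$met, sim$acc, scanParams())
  ctx <- al$features$context_class
  for (k in seq_len(nrow(gs$pseudobulk))) {
    g <- gs$pseudobulk$context[k]
    rows <- which(ctx == g)
    mx <- rowMeans(al$x[rows, , drop = FALSE], na.rm = TRUE)
    my <- rowMeans(al$y[rows, , drop = FALSE], na.rm = TRUE)
    mw <- rowMeans(al$w[rows, , drop = FALSE], na.rm = TRUE)
    ok <- which(is.finite(mx) & is.finite(my) & mw > 0)
    expect_equal(gs$pseudobulk$r[k],
                 weightedPearson(mx[ok], my[ok], mw[ok] / mean(mw[ok])),
                 tolerance = 1e-12)
  }
})
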