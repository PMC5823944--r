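mkSites <- function(pos, rate) {
  GRanges("chr1", IRanges(pos, width = 1L), strand = "+",
          n_meth = 0L, n_unmeth = 0L, context = "GpC",
          trinucleotide = "GCA", rate = rate)
}

test_that("pseudo-bulk windows have the right count and statistics", {
  region <- GRanges("chr1", IRanges(1L, 400L))
  cells <- list(a = mkSites(seq(5, 395, 10), 0.7),
                b = mkSites(seq(7, 397, 10), 0.7))
  pb <- pseudobulkProfile(cells, region, window = 50, step = 25)
  expect_equal(nrow(pb), 15L)
  expect_true(all(abs(pb$mean - 0.7) < 1e-12))
  expect_true(all(pb$sd == 0))
  expect_true(all(pb$n_cells == 2L))
  expect_error(pseudobulkProfile(cells, GRanges("chr1", IRanges(1, 40)),
                                 window = 50), "window")
})

test_that("expression strata split at 2 and 6 with boundaries in Medium", {
  x <- c(1.9, 2.0, 4, 6.0, 7)
  expect_equal(as.character(stratifyGenesByExpression(x)),
               c("Low", "Medium", "Medium", "Medium", "High"))
})

test_that("profiled-gene selection applies inclusive thresholds", {
  tss <- GRanges("chr1", IRanges(c(81L, 481L), width = 40L),
                 gene_id = c("gA", "gB"))
  ## gA: exactly 10 sites in 2 of 5 cells (40%); gB: 9 sites everywhere
  mk <- function(posList) lapply(posList, function(p)
    GRanges("chr1", IRanges(p, width = 1L), strand = "+",
            n_meth = 1L, n_unmeth = 1L, context = "GpC",
            trinucleotide = "GCA"))
  cells <- mk(list(c(85:94, 485:493), c(90:99, 485:493),
                   c(85:90, 485:493), c(85:89, 485:493),
                   c(85:88, 485:493)))
  names(cells) <- paste0("c", 1:5)
  keep <- selectProfiledGenes(cells, tss, minCellFrac = 0.4,
                              minSites = 10L)
  expect_equal(keep, "gA")
  expect_warning(selectProfiledGenes(cells, tss, minCellFrac = 1,
                                     minSites = 50L), "no gene")
  keepAll <- selectProfiledGenes(cells, tss, minCellFrac = 0,
                                 minSites = 1L)
  expect_setequal(keepAll, c("gA", "gB"))
})

test_that("profile fitting is saturating, symmetric and recovers truth", {
  b <- basisSet(9)
  xg <- seq(-1, 1, 0.02)
  ## saturated case
  set.seed(1)
  x <- runif(60, -1, 1)
  fit <- fitBprProfile(x, rep(1L, 60), rep(1L, 60), b)
  expect_true(all(profileCurve(fit$w, b, xg) >= 0.95))
  ## symmetric data give a symmetric curve
  xs <- c(-0.8, -0.5, -0.2, 0.2, 0.5, 0.8)
  ms <- c(1L, 3L, 0L, 0L, 3L, 1L)
  fit2 <- fitBprProfile(xs, ms, rep(4L, 6), b)
  curve <- profileCurve(fit2$w, b, xg)
  expect_lt(max(abs(curve - rev(curve))), 1e-6)
  ## generative recovery with 200 sites
  set.seed(2)
  wTrue <- c(0.3, rnorm(9, 0, 1))
  x <- runif(200, -1, 1)
  m <- rbinom(200, 4L, profileCurve(wTrue, b, x))
  fit3 <- fitBprProfile(x, m, rep(4L, 200), b)
  rmse <- sqrt(mean((profileCurve(fit3$w, b, xg) -
                       profileCurve(wTrue, b, xg))^2))
  expect_lt(rmse, 0.1)
  expect_true(fit3$converged)
})

test_that("the penalised probit objective is effectively concave", {
  ## different starts converge to the same curve
  b <- basisSet(9)
  xg <- seq(-1, 1, 0.05)
  set.seed(4)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    x <- runif(n, -1, 1)
    m <- rbinom(n, 3L, runif(1, 0.2, 0.8))
    H <- evalBasis(b, x)
    f1 <- scNOMe:::.probitFit(H, m, rep(3L, n))
    f2 <- scNOMe:::.probitFit(H, m, rep(3L, n),
                              winit = rnorm(10, 0, 0.5))
    expect_lt(max(abs(profileCurve(f1$w, b, xg) -
                        profileCurve(f2$w, b, xg))), 1e-6)
  }
})

test_that("mixture clustering selects the true K and assigns cells", {
  b <- basisSet(9)
  ## homogeneous cells -> K = 1, and the K = 1 model is the pooled fit
  mx1 <- simulateProfileMixture(30, K = 1, seed = 5)
  mr1 <- clusterProfiles(mx1$pdata, b, Kcandidates = 1:3, restarts = 2,
                         seed = 5)
  expect_equal(clusterK(mr1), 1L)
  pooled <- scNOMe:::.probitFit(
    evalBasis(b, unlist(lapply(mx1$pdata, `[[`, "x"))),
    unlist(lapply(mx1$pdata, `[[`, "m")),
    unlist(lapply(mx1$pdata, `[[`, "n")))
  expect_equal(mr1@logLik, pooled$logLik, tolerance = 1e-5)
  expect_true(all(is.finite(bicValues(mr1))))
  ## two separated groups -> K = 2 with accurate assignment
  mx2 <- simulateProfileMixture(40, K = 2, seed = 6)
  mr2 <- clusterProfiles(mx2$pdata, b, Kcandidates = 1:4, restarts = 3,
                         seed = 6)
  expect_equal(clusterK(mr2), 2L)
  tab <- table(clusterAssignments(mr2), mx2$labels)
  expect_gte(sum(apply(tab, 1, max)) / 40, 0.9)
})

test_that("heterogeneity report orders expression by cluster number", {
  mk <- function(gene, K) new("MixtureResult", geneId = gene,
    K = as.integer(K), bic = c(`1` = 0), assignments = c(a = 1L),
    clusterWeights = matrix(0, K, 10), mixProps = rep(1 / K, K),
    logLik = 0)
  mixes <- list(mk("g1", 1), mk("g2", 1), mk("g3", 2), mk("g4", 3))
  expr <- c(g1 = 8, g2 = 7, g3 = 3, g4 = 1)
  rep1 <- heterogeneityReport(mixes, expr)
  expect_equal(rep1$K, 1:3)
  expect_true(all(diff(rep1$median_expr) < 0))
  expect_false("prop_bivalent" %in% colnames(rep1))
  marks <- c(g1 = "none", g2 = "H3K4me3", g3 = "bivalent",
             g4 = "bivalent")
  rep2 <- heterogeneityReport(mixes, expr, marks)
  expect_equal(rep2$prop_bivalent, c(0, 1, 1))
  ## single K present -> one-row table
  expect_equal(nrow(heterogeneityReport(mixes[1:2], expr)), 1L)
})

test_that("expression prediction is exact for linear signal, null for noise", {
  set.seed(12)
  nG <- 80
  W <- cbind(1, matrix(rnorm(nG * 3), nG, 3))
  rownames(W) <- paste0("g", 1:nG)
  beta <- c(0.5, 2, -1, 1)
  y <- as.numeric(W %*% beta)
  expr <- matrix(y, nG, 1, dimnames = list(rownames(W), "cellA"))
  fl <- list(cellA = W[, -1])
  out <- suppressWarnings(predictExpression(fl, expr, folds = 5))
  expect_gte(out$r_cv, 0.99)
  ## permuted expression: no signal
  rs <- sapply(1:10, function(s) {
    set.seed(s)
    exprP <- expr
    exprP[, 1] <- sample(y)
    predictExpression(fl, exprP, folds = 5, seed = s)$r_cv
  })
  expect_lt(abs(median(rs)), 0.1)
  ## fewer genes than features errors
  expect_error(predictExpression(list(cellA = W[1:4, -1]),
                                 expr[1:4, , drop = FALSE]),
               "fewer genes")
})

test_that("Fisher enrichment matches the hypergeometric oracle", {
  universe <- paste0("g", 1:1000)
  query <- universe[1:50]
  set1 <- universe[c(1:10, 101:190)]        # 10 in query, 90 outside
  res <- fisherEnrichment(query, universe, list(s1 = set1))
  expect_equal(res$odds_ratio, (10 * 860) / (40 * 90), tolerance = 1e-12)
  expect_equal(res$p, fisherOracle(10, 40, 90, 860), tolerance = 1e-9)
  ## disjoint small set: odds ratio 0, p = 1
  res0 <- fisherEnrichment(query, universe,
                           list(s0 = universe[900:905]))
  expect_equal(res0$odds_ratio, 0)
  expect_equal(res0$p, 1, tolerance = 0.05)
  ## query = universe: nothing to enrich
  resU <- fisherEnrichment(universe, universe, list(s1 = set1))
  expect_equal(resU$p, 1)
  expect_error(fisherEnrichment(character(0), universe, list(s1 = set1)),
               "empty")
})
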