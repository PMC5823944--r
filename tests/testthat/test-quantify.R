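test_that("beta prior estimation recovers moments and degrades safely", {
  expect_equal(estimateBetaPrior(1:5, rep(10L, 5), method = "flat"),
               c(alpha = 1, beta = 1))
  ## all proportions 0 or 1 in equal number: spread at the maximum
  expect_warning(
    pr <- estimateBetaPrior(c(rep(0L, 10), rep(50L, 10)), rep(50L, 20)),
    "flat")
  expect_equal(pr, c(alpha = 1, beta = 1))
  ## recovery: theta ~ Beta(5,5), binomial n = 50, 1e4 sites
  set.seed(41)
  theta <- rbeta(1e4, 5, 5)
  m <- rbinom(1e4, 50, theta)
  pr <- estimateBetaPrior(m, rep(50L, 1e4))
  expect_lt(abs(pr["alpha"] - 5) / 5, 0.2)
  expect_lt(abs(pr["beta"] - 5) / 5, 0.2)
})

test_that("site MAP rates match beta-binomial closed forms", {
  expect_equal(siteRate(5, 10, 1, 1)$rate, 0.5)
  expect_equal(siteRate(3, 4, 2, 2)$rate, 4 / 6, tolerance = 1e-12)
  r <- siteRate(0, 3, 1, 1)
  expect_equal(r$rate, 0)
  expect_equal(r$se, sqrt(4 / (25 * 6)), tolerance = 1e-12)
  ## zero coverage is missing, not an error
  expect_true(is.na(siteRate(0, 0, 1, 1)$rate))
  ## MAP interpolates between prior mode and empirical proportion and
  ## converges to the proportion with coverage
  for (n in c(5, 50, 500)) {
    est <- siteRate(round(0.2 * n), n, 4, 2)$rate
    lo <- min(0.2, 3 / 4)
    hi <- max(0.2, 3 / 4)
    expect_true(est >= lo - 1e-9 && est <= hi + 1e-9)
  }
  expect_lt(abs(siteRate(100, 500, 4, 2)$rate - 0.2), 0.01)
  ## se shrinks monotonically with coverage at fixed rate
  ses <- siteRate(c(1, 10, 100), c(2, 20, 200), 1, 1)$se
  expect_true(all(diff(ses) < 0))
})

test_that("feature rates are inverse-variance weighted means", {
  g <- GRanges("chr1", IRanges(1, 100), feature_id = "f1",
               context_class = "promoter")
  mk <- function(pos, m, tot) GRanges("chr1", IRanges(pos, width = 1L),
    strand = "+", n_meth = m, n_unmeth = tot - m,
    context = "CpG", trinucleotide = "ACG")
  ## single site: feature equals the site
  rm1 <- quantifyFeatures(list(c1 = mk(10L, 3L, 4L)), g, "met",
                          prior = "flat")
  sr <- siteRate(3, 4, 1, 1)
  expect_equal(unname(rateValues(rm1)[1, 1]), sr$rate)
  expect_equal(unname(seValues(rm1)[1, 1]), sr$se)
  ## two sites with equal se, symmetric rates -> 0.5
  s2 <- mk(c(10L, 20L), c(1L, 4L), c(5L, 5L))
  rm2 <- quantifyFeatures(list(c1 = s2), g, "met", prior = "flat")
  expect_equal(unname(rateValues(rm2)[1, 1]), 0.5, tolerance = 1e-12)
  ## hand-computed inverse-variance mean with se (0.1, 0.1, 0.2)
  ivw <- (0 / 0.01 + 0 / 0.01 + 0.9 / 0.04) /
    (1 / 0.01 + 1 / 0.01 + 1 / 0.04)
  expect_equal(ivw, 0.1, tolerance = 1e-12)
})

test_that("feature/cell missingness matches an interval-overlap oracle", {
  set.seed(5)
  feats <- GRanges("chr1", IRanges(c(1L, 120L, 400L), width = 80L),
                   feature_id = c("f1", "f2", "f3"),
                   context_class = "promoter")
  cells <- lapply(1:3, function(i) randomSiteCalls(30, 500L, seed = i))
  names(cells) <- paste0("c", 1:3)
  rm <- quantifyFeatures(cells, feats, "met", prior = "flat")
  for (i in 1:3) for (j in 1:3) {
    s <- cells[[j]]
    covered <- sum(start(s) >= start(feats)[i] &
                     start(s) <= end(feats)[i] &
                     (s$n_meth + s$n_unmeth) >= 1L)
    expect_equal(unname(siteCounts(rm)[i, j]), covered)
    expect_equal(is.na(rateValues(rm)[i, j]), covered == 0L)
  }
  ## minSites masks low-coverage entries
  rm3 <- quantifyFeatures(cells, feats, "met", prior = "flat",
                          minSites = 100L)
  expect_true(all(is.na(rateValues(rm3))))
})

test_that("symmetric CpG strand merging combines paired calls only", {
  mk <- function(pos, str, m, tot) GRanges("chr1",
    IRanges(pos, width = 1L), strand = str, n_meth = m,
    n_unmeth = tot - m, context = "CpG",
    trinucleotide = ifelse(str == "+", "ACG", "TCG"))
  sites <- c(mk(10L, "+", 2L, 3L), mk(11L, "-", 1L, 2L),
             mk(50L, "+", 1L, 1L))
  merged <- mergeSymmetricCpG(sites)
  expect_length(merged, 2L)
  paired <- merged[start(merged) == 10L]
  expect_equal(paired$n_meth, 3L)
  expect_equal(paired$n_meth + paired$n_unmeth, 5L)
})

test_that("across-cell aggregation recovers between-cell spread", {
  g <- GRanges("chr1", IRanges(1, 100), feature_id = "f1",
               context_class = "promoter")
  mkRM <- function(rates, ses) {
    r <- matrix(rates, 1)
    s <- matrix(ses, 1)
    ns <- matrix(1L, 1, length(rates))
    colnames(r) <- colnames(s) <- colnames(ns) <-
      paste0("c", seq_along(rates))
    rownames(r) <- rownames(s) <- rownames(ns) <- "f1"
    se2 <- SummarizedExperiment::SummarizedExperiment(
      assays = list(rate = r, se = s, nSites = ns), rowRanges = g)
    S4Vectors::metadata(se2)$layer <- "met"
    new("RateMatrix", se2)
  }
  ## identical cells: mean = rate, tau = 0
  agg <- aggregateAcrossCells(mkRM(rep(0.4, 5), rep(0.05, 5)))
  expect_equal(agg$mean, 0.4)
  expect_equal(agg$sd, 0)
  ## symmetric two-cell case
  agg2 <- aggregateAcrossCells(mkRM(c(0, 1), c(0.1, 0.1)))
  expect_equal(agg2$mean, 0.5)
  ## single cell: mean only, sd flagged undefined
  agg1 <- aggregateAcrossCells(mkRM(0.3, 0.1))
  expect_false(agg1$sd_defined)
  ## recovery: true between-cell sd 0.2, se 0.05, 200 cells
  set.seed(9)
  y <- rnorm(200, 0.5, 0.2) + rnorm(200, 0, 0.05)
  agg3 <- aggregateAcrossCells(mkRM(pmin(1, pmax(0, y)), rep(0.05, 200)))
  expect_gt(agg3$sd, 0.17)
  expect_lt(agg3$sd, 0.23)
})

test_that("expression normalisation is depth-invariant", {
  counts <- matrix(c(4L, 10L, 0L, 8L, 20L, 0L), ncol = 2,
                   dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  norm <- normalizeExpression(counts)
  expect_equal(norm$logcounts[, "a"], norm$logcounts[, "b"])
  ## single cell: factor 1, pure log transform
  one <- normalizeExpression(counts[, 1, drop = FALSE])
  expect_equal(one$sizeFactors, 1)
  expect_equal(one$logcounts[, 1], log2(counts[, 1] + 1))
  ## all-zero cell errors with the cell named
  bad <- counts
  bad[, 2] <- 0L
  expect_error(normalizeExpression(bad), "b")
  ## Poisson depths 1x vs 4x: residual fold changes are small
  set.seed(21)
  mu <- runif(2000, 20, 200)
  cc <- cbind(x1 = rpois(2000, mu), x4 = rpois(2000, 4 * mu))
  rownames(cc) <- paste0("g", 1:2000)
  nl <- normalizeExpression(cc)$logcounts
  ## the systematic depth shift is removed (per-gene Poisson noise stays)
  expect_lt(abs(mean(nl[, 1] - nl[, 2])), 0.05)
})
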