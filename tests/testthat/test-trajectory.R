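test_that("overdispersed-gene ranking finds inflated-variance genes", {
  set.seed(31)
  nG <- 2000
  mu <- runif(nG, 1, 8)
  x <- matrix(rnorm(nG * 50, mu, 0.5), nG, 50)
  hot <- sample(nG, 50)
  x[hot, ] <- matrix(rnorm(50 * 50, mu[hot], 1.0), 50, 50)
  rownames(x) <- paste0("g", 1:nG)
  top <- overdispersedGenes(x, nTop = 500)
  expect_gte(sum(paste0("g", hot) %in% top), 45)
  ## constant genes are never selected
  x2 <- rbind(x, matrix(3, 5, 50,
                        dimnames = list(paste0("const", 1:5), NULL)))
  top2 <- suppressWarnings(overdispersedGenes(x2, nTop = nrow(x2)))
  expect_false(any(paste0("const", 1:5) %in% top2))
  ## asking for everything returns all informative genes
  expect_setequal(top2, rownames(x))
})

test_that("diffusion pseudotime recovers a latent trajectory", {
  cfg <- simConfig(nCells = 60, trajectory = TRUE)
  sim <- simulateFeatureRates(cfg, seed = 33)
  od <- suppressWarnings(overdispersedGenes(sim$logcounts, nTop = 50))
  pt <- diffusionPseudotime(sim$logcounts, od, marker = sim$truth$marker,
                            orientation = "decreasing")
  tau <- pseudotimeTau(pt)
  expect_equal(range(tau), c(0, 1))
  expect_gte(cor(tau, sim$truth$tau, method = "spearman"), 0.9)
  ## reversing the orientation flips tau exactly
  ptUp <- diffusionPseudotime(sim$logcounts, od,
                              marker = sim$truth$marker,
                              orientation = "increasing")
  expect_equal(pseudotimeTau(ptUp), 1 - tau)
  ## invariance to cell order (up to the marker-fixed orientation)
  perm <- sample(colnames(sim$logcounts))
  ptP <- diffusionPseudotime(sim$logcounts[, perm], od,
                             marker = sim$truth$marker,
                             orientation = "decreasing")
  expect_equal(pseudotimeTau(ptP)[names(tau)], tau, tolerance = 1e-9)
})

test_that("two subpopulations separate along pseudotime", {
  cfg <- simConfig(nCells = 60, trajectory = TRUE,
                   subpopProportions = c(0.5, 0.5))
  sim <- simulateFeatureRates(cfg, seed = 35)
  od <- suppressWarnings(overdispersedGenes(sim$logcounts, nTop = 50))
  pt <- diffusionPseudotime(sim$logcounts, od, marker = sim$truth$marker,
                            orientation = "decreasing")
  tau <- pseudotimeTau(pt)
  lab <- sim$truth$tau > 0.5
  ranks <- rank(tau)
  auc <- (sum(ranks[lab]) - sum(lab) * (sum(lab) + 1) / 2) /
    (sum(lab) * sum(!lab))
  expect_gte(max(auc, 1 - auc), 0.9)
})

test_that("profile dynamics along pseudotime are detected and calibrated", {
  b <- basisSet(9)
  set.seed(44)
  nCells <- 30
  tau <- seq(0, 1, length.out = nCells)
  names(tau) <- sprintf("c%02d", 1:nCells)
  ## NDR closes monotonically along tau
  mkFits <- function(depths) {
    pdata <- lapply(seq_len(nCells), function(i) {
      x <- sort(runif(20, -1, 1))
      p <- pmin(0.95, pmax(0.05, 0.2 + depths[i] * exp(-x^2 / 0.2)))
      data.frame(x = x, m = rbinom(20, 4, p), n = 4)
    })
    names(pdata) <- names(tau)
    fitProfileSet(pdata, b, geneId = "gX")
  }
  fitsDyn <- mkFits(0.7 * (1 - tau))
  res <- profileTrajectoryAssociation(list(fitsDyn), tau, nPerm = 200,
                                      minCells = 20)
  expect_lt(res$p, 0.05)
  expect_true(res$sig)
  ## sign is stable across permutation seeds
  res2 <- profileTrajectoryAssociation(list(fitsDyn), tau, nPerm = 200,
                                       seed = 99)
  expect_equal(sign(res$statistic), sign(res2$statistic))
  ## nPerm = 0 returns the statistic without a p-value
  res0 <- profileTrajectoryAssociation(list(fitsDyn), tau, nPerm = 0)
  expect_true(is.na(res0$p))
  expect_false(is.na(res0$statistic))
  ## null calibration: tau-independent profiles
  rej <- sapply(1:20, function(s) {
    set.seed(s)
    fitsNull <- mkFits(rep(0.4, nCells))
    r <- profileTrajectoryAssociation(list(fitsNull), tau, nPerm = 200,
                                      seed = s)
    r$p < 0.1
  })
  expect_lte(mean(rej), 0.12 + 0.1)   # 1 gene/seed: generous MC slack
})

test_that("coupling trend along pseudotime behaves under signal and null", {
  set.seed(51)
  nCells <- 60
  tau <- setNames(runif(nCells), sprintf("c%02d", 1:nCells))
  ## ramped coupling: per-cell r decreases with tau
  perCell <- data.frame(
    cell_id = rep(names(tau), 2),
    context = rep(c("promoter", "gene_body"), each = nCells),
    r = rep(-0.6 * tau, 2) + rnorm(2 * nCells, 0, 0.1))
  tr <- couplingVsPseudotime(perCell, tau)
  expect_true(all(tr$trend < 0))
  expect_true(all(tr$p < 0.05))
  ## identical inputs give identical outputs per context
  expect_equal(tr$trend[1], tr$trend[2], tolerance = 0.2)
  perCell2 <- perCell
  perCell2$r <- rep(perCell$r[1:nCells], 2)
  tr2 <- couplingVsPseudotime(perCell2, tau)
  expect_equal(tr2$trend[1], tr2$trend[2], tolerance = 1e-12)
  ## constant coupling: trend defined as zero
  perCell3 <- perCell
  perCell3$r <- -0.3
  tr3 <- couplingVsPseudotime(perCell3, tau)
  expect_true(all(tr3$trend == 0))
  ## too few cells: context skipped
  expect_equal(nrow(couplingVsPseudotime(perCell[1:5, ], tau)), 0L)
})
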