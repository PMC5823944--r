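## Mixture-of-profiles clustering by EM with a shared Bernoulli/probit
## basis-function likelihood. Each cluster k owns a weight vector over the
## basis; a cell's likelihood under cluster k is the binomial likelihood of
## its observed GpC states under the cluster curve (so deeper-covered cells
## naturally carry more weight).

.cellLogLik <- function(pdata, Hs, w) {
  vapply(seq_along(pdata), function(i) {
    eta <- pmin(7, pmax(-7, as.numeric(Hs[[i]] %*% w)))
    .binomLogLik(eta, pdata[[i]]$m, pdata[[i]]$n)
  }, numeric(1))
}

.emOnce <- function(pdata, Hs, K, init, lambda, maxit, tol) {
  N <- length(pdata)
  d <- ncol(Hs[[1L]])
  Hall <- do.call(rbind, Hs)
  mAll <- unlist(lapply(pdata, `[[`, "m"))
  nAll <- unlist(lapply(pdata, `[[`, "n"))
  sizes <- vapply(pdata, nrow, integer(1))
  cellIdx <- rep(seq_len(N), sizes)
  W <- init$W            # K x d cluster weights
  pik <- init$pi
  llMat <- matrix(0, N, K)
  llPrev <- -Inf
  for (it in seq_len(maxit)) {
    for (k in seq_len(K)) llMat[, k] <- .cellLogLik(pdata, Hs, W[k, ])
    lw <- sweep(llMat, 2, log(pik), "+")
    mx <- apply(lw, 1, max)
    resp <- exp(lw - mx)
    rs <- rowSums(resp)
    resp <- resp / rs
    ll <- sum(mx + log(rs))
    pik <- colMeans(resp)
    if (any(pik < 1e-8)) return(list(degenerate = TRUE))
    for (k in seq_len(K)) {
      obsw <- resp[cellIdx, k]
      fit <- .probitFit(Hall, mAll, nAll, lambda = lambda, obsw = obsw,
                        winit = W[k, ], maxit = 25L, tol = 1e-8)
      W[k, ] <- fit$w
    }
    if (is.finite(llPrev) && abs(ll - llPrev) < tol * (abs(ll) + 1)) break
    llPrev <- ll
  }
  for (k in seq_len(K)) llMat[, k] <- .cellLogLik(pdata, Hs, W[k, ])
  lw <- sweep(llMat, 2, log(pik), "+")
  mx <- apply(lw, 1, max)
  ll <- sum(mx + log(rowSums(exp(lw - mx))))
  list(degenerate = FALSE, W = W, pi = pik, logLik = ll,
       assignments = max.col(lw))
}

#' Cluster single-cell accessibility profiles at one gene
#'
#' Fits finite mixtures of basis-weight profiles by EM for each candidate
#' number of clusters K, with multiple restarts initialised by k-means on
#' the per-cell fitted weight vectors. The number of clusters is chosen by
#' the Bayesian Information Criterion, BIC = -2 logL + p log(N) with
#' p = K(M+1) + (K-1) free parameters and N the number of cells; ties go to
#' the smallest K. Restarts that collapse a cluster are discarded; a K for
#' which every restart degenerates is excluded.
#'
#' The RNG seed is set internally (from \code{seed}, per K and restart) so
#' results are reproducible.
#'
#' @param pdata per-cell observations from \code{\link{extractProfileData}}
#'   (>= 2 cells).
#' @param basis a \linkS4class{BasisSet}.
#' @param Kcandidates candidate cluster numbers.
#' @param restarts EM restarts per K.
#' @param lambda L2 penalty inside the cluster-profile fits.
#' @param maxit,tol EM convergence controls.
#' @param seed base RNG seed.
#' @param geneId identifier recorded in the result.
#' @param fits optional precomputed \linkS4class{ProfileFitSet} for the
#'   same cells (speeds up initialisation).
#' @return A \linkS4class{MixtureResult}.
#' @export
clusterProfiles <- function(pdata, basis = basisSet(), Kcandidates = 1:6,
                            restarts = 5L, lambda = 0.01, maxit = 200L,
                            tol = 1e-6, seed = 1L, geneId = "gene",
                            fits = NULL) {
  N <- length(pdata)
  stopifnot(N >= 2L)
  if (is.null(fits))
    fits <- fitProfileSet(pdata, basis, lambda, geneId)
  Wcell <- profileWeights(fits)
  Hs <- lapply(pdata, function(df) evalBasis(basis, df$x))
  d <- basis@M + 1L
  Kcandidates <- sort(unique(as.integer(Kcandidates)))
  Kcandidates <- Kcandidates[Kcandidates >= 1L & Kcandidates <= N]
  bic <- setNames(rep(NA_real_, length(Kcandidates)),
                  as.character(Kcandidates))
  best <- list()
  for (K in Kcandidates) {
    bestLL <- -Inf
    bestRun <- NULL
    nR <- if (K == 1L) 1L else restarts
    for (r in seq_len(nR)) {
      set.seed(seed * 1000L + K * 100L + r)
      if (K == 1L) {
        cl <- rep(1L, N)
      } else {
        km <- tryCatch(kmeans(Wcell, centers = K, nstart = 1L),
                       error = function(e) NULL)
        cl <- if (is.null(km)) sample(rep_len(seq_len(K), N)) else km$cluster
      }
      W0 <- matrix(0, K, d)
      for (k in seq_len(K)) {
        sel <- which(cl == k)
        if (!length(sel)) sel <- sample(N, 1L)
        W0[k, ] <- colMeans(Wcell[sel, , drop = FALSE])
      }
      run <- .emOnce(pdata, Hs, K, list(W = W0, pi = rep(1 / K, K)),
                     lambda, maxit, tol)
      if (!run$degenerate && run$logLik > bestLL) {
        bestLL <- run$logLik
        bestRun <- run
      }
    }
    if (!is.null(bestRun)) {
      p <- K * d + (K - 1L)
      bic[as.character(K)] <- -2 * bestRun$logLik + p * log(N)
      best[[as.character(K)]] <- bestRun
    }
  }
  if (all(is.na(bic))) stop("all candidate K degenerate")
  Ksel <- Kcandidates[which.min(bic)]   # which.min takes the first minimum
  run <- best[[as.character(Ksel)]]
  new("MixtureResult", geneId = geneId, K = as.integer(Ksel), bic = bic,
      assignments = setNames(as.integer(run$assignments), names(pdata)),
      clusterWeights = run$W, mixProps = run$pi, logLik = run$logLik)
}

#' @rdname clusterK
#' @export
clusterAssignments <- function(x) x@assignments

#' Accessors for mixture results
#'
#' @param x a \linkS4class{MixtureResult}.
#' @return Chosen K, BIC vector, or cluster assignments.
#' @name clusterK
#' @export
clusterK <- function(x) x@K

#' @rdname clusterK
#' @export
bicValues <- function(x) x@bic

#' @importFrom stats kmeans setNames dnorm
NULL
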