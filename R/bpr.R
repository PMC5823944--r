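#' Construct a radial basis set
#'
#' M Gaussian radial basis functions with centres equally spaced on
#' [-1, 1] and a common width equal to the centre spacing, plus an
#' intercept handled by the design matrix.
#'
#' @param M number of radial basis functions (default 9).
#' @param gammaScale width as a multiple of the centre spacing.
#' @return A \linkS4class{BasisSet}.
#' @export
basisSet <- function(M = 9L, gammaScale = 1.0) {
  M <- as.integer(M)
  centres <- if (M == 1L) 0 else seq(-1, 1, length.out = M)
  spacing <- if (M == 1L) 1 else centres[2L] - centres[1L]
  new("BasisSet", M = M, centres = centres, gamma = spacing * gammaScale)
}

#' Evaluate the basis design matrix
#'
#' @param basis a \linkS4class{BasisSet}.
#' @param x positions scaled to [-1, 1].
#' @return Matrix with an intercept column followed by M Gaussian columns.
#' @export
evalBasis <- function(basis, x) {
  H <- vapply(basis@centres,
              function(c) exp(-(x - c)^2 / (2 * basis@gamma^2)),
              numeric(length(x)))
  if (!is.matrix(H)) H <- matrix(H, nrow = length(x))
  cbind(1, H)
}

.binomLogLik <- function(eta, m, n, obsw = 1) {
  p <- pmin(1 - 1e-10, pmax(1e-10, pnorm(eta)))
  sum(obsw * (m * log(p) + (n - m) * log(1 - p)))
}

## Penalised binomial probit regression by Fisher scoring. obsw are
## per-observation multipliers (EM responsibilities); the L2 penalty with
## strength lambda applies to all non-intercept weights. The objective is
## strictly concave, so the fit is deterministic.
.probitFit <- function(H, m, n, lambda = 0.01, obsw = 1, winit = NULL,
                       maxit = 100L, tol = 1e-11) {
  d <- ncol(H)
  obsw <- rep_len(obsw, nrow(H))
  pen <- diag(c(0, rep(lambda, d - 1L)), d)
  w <- if (is.null(winit)) rep(0, d) else winit
  llPrev <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- pmin(7, pmax(-7, as.numeric(H %*% w)))
    p <- pmin(1 - 1e-10, pmax(1e-10, pnorm(eta)))
    phi <- pmax(dnorm(eta), 1e-10)
    Wk <- obsw * n * phi^2 / (p * (1 - p))
    z <- eta + (m / pmax(n, 1e-12) - p) / phi
    A <- crossprod(H, Wk * H) + pen
    b <- crossprod(H, Wk * z)
    wNew <- tryCatch(solve(A, b),
                     error = function(e) solve(A + diag(1e-8, d), b))
    wNew <- as.numeric(wNew)
    etaN <- pmin(7, pmax(-7, as.numeric(H %*% wNew)))
    ll <- .binomLogLik(etaN, m, n, obsw) -
      0.5 * lambda * sum(wNew[-1L]^2)
    ## step-halve if the penalised objective decreased (guards the
    ## quadratic approximation at extreme eta)
    step <- 1
    while (ll < llPrev - 1e-12 && step > 1e-4) {
      step <- step / 2
      wNew <- w + step * (wNew - w)
      etaN <- pmin(7, pmax(-7, as.numeric(H %*% wNew)))
      ll <- .binomLogLik(etaN, m, n, obsw) -
        0.5 * lambda * sum(wNew[-1L]^2)
    }
    delta <- max(abs(wNew - w))
    w <- wNew
    if (is.finite(llPrev) && (abs(ll - llPrev) < tol * (abs(ll) + 1) ||
                              delta < 1e-10)) {
      converged <- TRUE
      llPrev <- ll
      break
    }
    llPrev <- ll
  }
  eta <- pmin(7, pmax(-7, as.numeric(H %*% w)))
  list(w = w, logLik = .binomLogLik(eta, m, n, obsw),
       penLogLik = llPrev, converged = converged)
}

#' Fit a single-cell accessibility profile
#'
#' Bernoulli (binomial, for multi-read sites) basis-function regression
#' with a probit link: the probability that a GpC site at scaled position x
#' is accessible is \code{pnorm(h(x) %*% w)} where h(x) is the radial basis
#' expansion. Weights maximise the L2-penalised log-likelihood; the
#' objective is concave, so the fit is deterministic.
#'
#' @param x site positions scaled to [-1, 1].
#' @param nMeth methylated (accessible) read counts per site.
#' @param nTotal total read counts per site, >= 1.
#' @param basis a \linkS4class{BasisSet}.
#' @param lambda L2 penalty on non-intercept weights.
#' @return List with \code{w} (weights, intercept first), \code{logLik}
#'   (unpenalised), \code{converged}.
#' @export
fitBprProfile <- function(x, nMeth, nTotal, basis = basisSet(),
                          lambda = 0.01) {
  stopifnot(length(x) == length(nMeth), length(x) == length(nTotal),
            all(nTotal >= 1L), all(nMeth <= nTotal))
  H <- evalBasis(basis, x)
  .probitFit(H, nMeth, nTotal, lambda = lambda)
}

#' Evaluate a fitted profile curve
#'
#' @param w weight vector (intercept first).
#' @param basis the \linkS4class{BasisSet} used for fitting.
#' @param x scaled positions at which to evaluate.
#' @return Fitted accessibility probabilities in [0, 1].
#' @export
profileCurve <- function(w, basis, x) {
  as.numeric(pnorm(evalBasis(basis, x) %*% w))
}

#' Extract per-cell profile observations for one TSS window
#'
#' Positions are scaled so the window maps to [-1, 1], oriented 5' to 3'
#' relative to the gene (minus-strand windows are mirrored). Only covered
#' sites (>= 1 read) are returned; cells with fewer than \code{minSites}
#' covered sites are dropped.
#'
#' @param cellSites named list of GpC-channel site-call GRanges.
#' @param window GRanges of length 1 (the TSS window, strand-aware).
#' @param minSites minimum covered sites per cell.
#' @return Named list per retained cell of data.frames (x, m, n).
#' @export
extractProfileData <- function(cellSites, window, minSites = 10L) {
  stopifnot(length(window) == 1L)
  centre <- (start(window) + end(window)) / 2
  half <- (end(window) - start(window)) / 2
  minusStrand <- as.character(strand(window)) == "-"
  out <- list()
  for (cell in names(cellSites)) {
    s <- cellSites[[cell]]
    s <- s[as.character(seqnames(s)) == as.character(seqnames(window)) &
             start(s) >= start(window) & start(s) <= end(window)]
    tot <- s$n_meth + s$n_unmeth
    s <- s[tot >= 1L]
    if (length(s) < minSites) next
    x <- (start(s) - centre) / half
    if (minusStrand) x <- -x
    out[[cell]] <- data.frame(x = x, m = s$n_meth,
                              n = s$n_meth + s$n_unmeth)
  }
  out
}

#' Fit accessibility profiles for all cells at one gene
#'
#' @param pdata per-cell observations from \code{\link{extractProfileData}}.
#' @param basis a \linkS4class{BasisSet}.
#' @param lambda L2 penalty.
#' @param geneId gene identifier recorded in the result.
#' @return A \linkS4class{ProfileFitSet}.
#' @export
fitProfileSet <- function(pdata, basis = basisSet(), lambda = 0.01,
                          geneId = "gene") {
  cells <- names(pdata)
  d <- basis@M + 1L
  W <- matrix(NA_real_, length(cells), d)
  ll <- numeric(length(cells))
  ns <- integer(length(cells))
  conv <- logical(length(cells))
  for (i in seq_along(cells)) {
    df <- pdata[[i]]
    fit <- fitBprProfile(df$x, df$m, df$n, basis, lambda)
    W[i, ] <- fit$w
    ll[i] <- fit$logLik
    ns[i] <- nrow(df)
    conv[i] <- fit$converged
  }
  rownames(W) <- cells
  new("ProfileFitSet", geneId = geneId, cellIds = cells, weights = W,
      logLik = ll, nSites = ns, converged = conv, basis = basis)
}

#' @rdname profileWeights
#' @export
profileWeights <- function(x) x@weights

#' Accessors for profile fits
#'
#' @param x a \linkS4class{ProfileFitSet}.
#' @return Matrix of per-cell basis weights, or the BasisSet.
#' @name profileWeights
#' @export
profileBasis <- function(x) x@basis
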