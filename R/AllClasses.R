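#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowRanges rowRanges<- colData colData<-
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' ContextCensus: trinucleotide census of a genome
#'
#' Exhaustive classification of every cytosine in a genome (both strands)
#' into the NOMe channels: CpG kept (A-C-G / T-C-G), CpG excluded because
#' the upstream base is G (G-C-G, ambiguous between endogenous and enzymatic
#' methylation) or C (C-C-G, enzyme off-target risk), GpC kept
#' (G-C-A / G-C-C / G-C-T), or neither channel.
#'
#' @slot counts integer matrix, context label x strand, cytosine counts.
#' @slot dinucleotides named numeric: total CpG and GpC dinucleotide
#'   occurrences (plus strand occurrences of the 2-mers "CG" and "GC").
#' @slot gpcSpacing named numeric: mean distance in bp between consecutive
#'   GpC dinucleotide starts, per chromosome.
#' @slot nScanned total number of cytosines scanned (both strands).
#' @exportClass ContextCensus
setClass("ContextCensus",
  representation(
    counts = "matrix",
    dinucleotides = "numeric",
    gpcSpacing = "numeric",
    nScanned = "numeric"
  )
)

setValidity("ContextCensus", function(object) {
  msg <- NULL
  if (!all(contextLabels() %in% rownames(object@counts)))
    msg <- c(msg, "counts must have one row per context label")
  if (!setequal(colnames(object@counts), c("+", "-")))
    msg <- c(msg, "counts must have columns '+' and '-'")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (abs(sum(object@counts) - object@nScanned) > 0.5)
    msg <- c(msg, "counts must sum to nScanned")
  if (is.null(msg)) TRUE else msg
})

#' The vocabulary of cytosine context labels
#'
#' @return Character vector of the five context labels.
#' @export
contextLabels <- function() {
  c("CG_KEPT", "CG_EXCLUDED_GCG", "CG_EXCLUDED_CCG", "GC_KEPT", "NONE")
}

#' RateMatrix: per-feature, per-cell epigenetic rates
#'
#' A \linkS4class{SummarizedExperiment} with assays \code{rate} (MAP rate in
#' [0,1], NA where a feature is not covered in a cell), \code{se} (posterior
#' standard error of the feature rate) and \code{nSites} (number of covered
#' cytosines entering the estimate). Rows are genomic features (with
#' \code{context_class} and optionally \code{gene_id} in the row metadata),
#' columns are cells. The layer ("met" or "acc") is stored in
#' \code{metadata(x)$layer}.
#'
#' @exportClass RateMatrix
setClass("RateMatrix", contains = "RangedSummarizedExperiment")

setValidity("RateMatrix", function(object) {
  msg <- NULL
  need <- c("rate", "se", "nSites")
  if (!all(need %in% assayNames(object)))
    msg <- c(msg, "assays 'rate', 'se' and 'nSites' are required")
  else {
    r <- assay(object, "rate")
    ns <- assay(object, "nSites")
    if (any(r < -1e-9 | r > 1 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "rates must lie in [0,1]")
    if (any(is.na(r) != (is.na(ns) | ns == 0)))
      msg <- c(msg, "missingness of 'rate' must match zero site coverage")
  }
  lay <- metadata(object)$layer
  if (!is.null(lay) && !lay %in% c("met", "acc"))
    msg <- c(msg, "metadata layer must be 'met' or 'acc'")
  if (is.null(msg)) TRUE else msg
})

#' BasisSet: radial basis functions over a scaled window
#'
#' Gaussian radial basis functions with centres equally spaced on [-1, 1]
#' plus an intercept, used for Bernoulli accessibility-profile regression.
#'
#' @slot M number of radial basis functions (excludes the intercept).
#' @slot centres numeric, sorted centres in [-1, 1].
#' @slot gamma common width (standard deviation) of the Gaussians.
#' @exportClass BasisSet
setClass("BasisSet",
  representation(M = "integer", centres = "numeric", gamma = "numeric")
)

setValidity("BasisSet", function(object) {
  msg <- NULL
  if (object@M < 1L) msg <- c(msg, "M must be >= 1")
  if (length(object@centres) != object@M) msg <- c(msg, "length(centres) != M")
  if (is.unsorted(object@centres)) msg <- c(msg, "centres must be sorted")
  if (object@gamma <= 0) msg <- c(msg, "gamma must be positive")
  if (is.null(msg)) TRUE else msg
})

#' ProfileFitSet: fitted accessibility profiles for one gene
#'
#' Per-cell Bernoulli basis-function regression fits in one TSS window.
#'
#' @slot geneId gene identifier.
#' @slot cellIds character, one per fitted cell.
#' @slot weights numeric matrix, cells x (M + 1) fitted basis weights
#'   (intercept first).
#' @slot logLik numeric, unpenalised Bernoulli log-likelihood per cell.
#' @slot nSites integer, observations used per cell.
#' @slot converged logical per cell.
#' @slot basis the \linkS4class{BasisSet} used.
#' @exportClass ProfileFitSet
setClass("ProfileFitSet",
  representation(
    geneId = "character", cellIds = "character", weights = "matrix",
    logLik = "numeric", nSites = "integer", converged = "logical",
    basis = "BasisSet"
  )
)

setValidity("ProfileFitSet", function(object) {
  n <- length(object@cellIds)
  msg <- NULL
  if (nrow(object@weights) != n || length(object@logLik) != n ||
      length(object@nSites) != n || length(object@converged) != n)
    msg <- c(msg, "per-cell slots must agree in length")
  if (ncol(object@weights) != object@basis@M + 1L)
    msg <- c(msg, "weights must have M + 1 columns")
  if (is.null(msg)) TRUE else msg
})

#' MixtureResult: EM mixture clustering of accessibility profiles
#'
#' @slot geneId gene identifier.
#' @slot K chosen number of clusters (minimum-BIC, ties to the smallest K).
#' @slot bic named numeric, BIC per attempted K.
#' @slot assignments named integer, cell -> cluster.
#' @slot clusterWeights numeric matrix, K x (M + 1) cluster profile weights.
#' @slot mixProps numeric, mixing proportions.
#' @slot logLik mixture log-likelihood at the chosen K.
#' @exportClass MixtureResult
setClass("MixtureResult",
  representation(
    geneId = "character", K = "integer", bic = "numeric",
    assignments = "integer", clusterWeights = "matrix",
    mixProps = "numeric", logLik = "numeric"
  )
)

setValidity("MixtureResult", function(object) {
  msg <- NULL
  if (length(object@K) == 1L && !is.na(object@K)) {
    if (nrow(object@clusterWeights) != object@K)
      msg <- c(msg, "clusterWeights must have K rows")
    if (any(object@assignments < 1L | object@assignments > object@K))
      msg <- c(msg, "assignments must be in 1..K")
  }
  if (is.null(msg)) TRUE else msg
})

#' PseudotimeResult: diffusion-map ordering of cells
#'
#' @slot tau named numeric, per-cell pseudotime in [0, 1].
#' @slot components numeric matrix, cells x diffusion components.
#' @slot genes character, genes used to build the map.
#' @slot marker orientation marker gene.
#' @slot orientation "decreasing" or "increasing" expected for the marker.
#' @exportClass PseudotimeResult
setClass("PseudotimeResult",
  representation(
    tau = "numeric", components = "matrix", genes = "character",
    marker = "character", orientation = "character"
  )
)

setValidity("PseudotimeResult", function(object) {
  msg <- NULL
  if (length(object@tau) > 1 &&
      (abs(min(object@tau)) > 1e-9 || abs(max(object@tau) - 1) > 1e-9))
    msg <- c(msg, "tau must span [0, 1]")
  if (nrow(object@components) != length(object@tau))
    msg <- c(msg, "components rows must match tau")
  if (is.null(msg)) TRUE else msg
})

#' SimConfig: parameters of the synthetic single-cell NOMe-seq generator
#'
#' Validated parameter container; construct with \code{\link{simConfig}}.
#'
#' @slot params named list of generator parameters.
#' @exportClass SimConfig
setClass("SimConfig", representation(params = "list"))

setValidity("SimConfig", function(object) {
  p <- object@params
  msg <- NULL
  probs <- c("accHigh", "accLow", "siteCoverageProb", "conversionError",
             "ndrOpenStart", "ndrOpenEnd")
  for (nm in probs)
    if (!is.null(p[[nm]]) && (p[[nm]] < 0 || p[[nm]] > 1))
      msg <- c(msg, paste0(nm, " must be a probability in [0,1]"))
  if (p$nucleosomeRepeat <= 0) msg <- c(msg, "nucleosomeRepeat must be > 0")
  for (nm in c("rhoMA", "rhoME", "rhoAE"))
    if (abs(p[[nm]]) > 1) msg <- c(msg, paste0(nm, " must be in [-1,1]"))
  if (p$rhoMA > 0) msg <- c(msg, "rhoMA must be <= 0")
  if (p$rhoME > 0) msg <- c(msg, "rhoME must be <= 0")
  if (p$rhoAE < 0) msg <- c(msg, "rhoAE must be >= 0")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ContextCensus", function(object) {
  cat("ContextCensus over", format(object@nScanned, big.mark = ","),
      "cytosines\n")
  print(object@counts)
  cat("CpG dinucleotides:", object@dinucleotides[["CpG"]],
      " GpC dinucleotides:", object@dinucleotides[["GpC"]], "\n")
  cat("mean GpC spacing (bp):",
      paste(sprintf("%s=%.2f", names(object@gpcSpacing), object@gpcSpacing),
            collapse = ", "), "\n")
})

setMethod("show", "RateMatrix", function(object) {
  cat("RateMatrix (layer:", metadata(object)$layer %||% "?", ") ",
      nrow(object), " features x ", ncol(object), " cells; ",
      sprintf("%.1f%%", 100 * mean(is.na(assay(object, "rate")))),
      " missing\n", sep = "")
})

setMethod("show", "ProfileFitSet", function(object) {
  cat("ProfileFitSet for gene", object@geneId, ":",
      length(object@cellIds), "cells,", object@basis@M,
      "basis functions\n")
})

setMethod("show", "MixtureResult", function(object) {
  cat("MixtureResult for gene", object@geneId, ": K =", object@K,
      "(BIC over K:", paste(names(object@bic), round(object@bic, 1),
                            sep = "=", collapse = " "), ")\n")
})

setMethod("show", "PseudotimeResult", function(object) {
  cat("PseudotimeResult:", length(object@tau), "cells, oriented by",
      object@marker, paste0("(", object@orientation, ")\n"))
})

setMethod("show", "SimConfig", function(object) {
  p <- object@params
  cat("SimConfig:", p$nCells, "cells, genome", p$genomeLength, "bp,",
      p$nGenes, "genes; rhoMA =", p$rhoMA, "rhoME =", p$rhoME,
      "rhoAE =", p$rhoAE, "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
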