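#' Quality-control threshold presets
#'
#' Two presets mirroring the study conditions of serum-grown ES cells
#' ("es": deeper sequencing, stricter coverage cut-offs) and embryoid-body
#' cells ("eb": shallower sequencing, relaxed coverage cut-offs). RNA-layer
#' thresholds: minimum mapped reads, maximum mitochondrial read fraction,
#' minimum genes expressed. Bisulfite-layer thresholds: minimum mapping
#' efficiency, minimum CpG and GpC sites covered. A NA threshold is
#' disabled.
#'
#' @param preset "es" or "eb".
#' @return Named list of thresholds.
#' @export
qcPresets <- function(preset = c("es", "eb")) {
  preset <- match.arg(preset)
  if (preset == "es") {
    list(minMappedReads = 3e5, maxMitoFraction = 0.15,
         minGenesExpressed = 2000, minMappingEfficiency = 0.10,
         minCpGSites = 5e5, minGpCSites = 5e6)
  } else {
    list(minMappedReads = 1e5, maxMitoFraction = 0.15,
         minGenesExpressed = 2000, minMappingEfficiency = 0.10,
         minCpGSites = 3e5, minGpCSites = NA_real_)
  }
}

.QC_FIELDS <- c(minMappedReads = "mapped_reads",
                maxMitoFraction = "mito_fraction",
                minGenesExpressed = "genes_expressed",
                minMappingEfficiency = "mapping_efficiency",
                minCpGSites = "cpg_sites",
                minGpCSites = "gpc_sites")

.QC_LAYER <- c(minMappedReads = "rna", maxMitoFraction = "rna",
               minGenesExpressed = "rna", minMappingEfficiency = "bs",
               minCpGSites = "bs", minGpCSites = "bs")

#' Per-cell quality-control filtering
#'
#' A cell passes a layer iff it violates none of that layer's active
#' thresholds; the combined pass requires both layers. Upper-bound
#' thresholds (mitochondrial fraction) fail cells strictly above the
#' threshold; lower-bound thresholds fail cells strictly below.
#'
#' @param cellStats data.frame with a \code{cell_id} column and the
#'   statistics named in the active thresholds (mapped_reads,
#'   mito_fraction, genes_expressed, mapping_efficiency, cpg_sites,
#'   gpc_sites).
#' @param thresholds named list as produced by \code{\link{qcPresets}};
#'   NA or NULL entries are disabled.
#' @return data.frame with cell_id, pass_rna, pass_bs, pass and
#'   fail_reasons (comma-separated); attribute \code{"failCounts"} tallies
#'   cells failing each threshold.
#' @export
qcFilter <- function(cellStats, thresholds) {
  stopifnot("cell_id" %in% colnames(cellStats))
  active <- names(thresholds)[!vapply(thresholds,
                                      function(t) is.null(t) || is.na(t),
                                      logical(1))]
  active <- intersect(active, names(.QC_FIELDS))
  n <- nrow(cellStats)
  fails <- matrix(FALSE, n, length(active),
                  dimnames = list(cellStats$cell_id, active))
  for (th in active) {
    field <- .QC_FIELDS[[th]]
    if (!field %in% colnames(cellStats))
      stop("threshold ", th, " is active but statistic '", field,
           "' is missing")
    x <- cellStats[[field]]
    if (any(is.na(x)))
      stop("missing '", field, "' for cell ",
           cellStats$cell_id[which(is.na(x))[1L]])
    cut <- thresholds[[th]]
    fails[, th] <- if (startsWith(th, "max")) x > cut else x < cut
  }
  layerOf <- .QC_LAYER[active]
  passRna <- !apply(fails[, layerOf == "rna", drop = FALSE], 1, any)
  passBs <- !apply(fails[, layerOf == "bs", drop = FALSE], 1, any)
  reasons <- apply(fails, 1, function(f)
    paste(active[f], collapse = ","))
  out <- data.frame(cell_id = cellStats$cell_id,
                    pass_rna = passRna, pass_bs = passBs,
                    pass = passRna & passBs,
                    fail_reasons = unname(reasons),
                    stringsAsFactors = FALSE)
  attr(out, "failCounts") <- colSums(fails)
  out
}
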