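#' @importFrom GenomicRanges GRanges start end width strand seqnames
#'   findOverlaps mcols
#' @importFrom IRanges IRanges
#' @importFrom utils read.delim write.table
NULL

.SITECALL_MCOLS <- c("n_meth", "n_unmeth", "context", "trinucleotide")

#' Validate a collection of site calls
#'
#' Site calls are represented as a width-1 \link[GenomicRanges]{GRanges}
#' with metadata columns \code{n_meth}, \code{n_unmeth}, \code{context}
#' and \code{trinucleotide}. Positions are 1-based and refer to the
#' cytosine on its own strand.
#'
#' @param sites GRanges of site calls.
#' @return Invisibly \code{TRUE}; errors describe the first violation.
#' @export
validateSiteCalls <- function(sites) {
  if (!is(sites, "GRanges"))
    stop("site calls must be a GRanges")
  miss <- setdiff(.SITECALL_MCOLS, colnames(mcols(sites)))
  if (length(miss))
    stop("site calls are missing metadata columns: ",
         paste(miss, collapse = ", "))
  if (length(sites)) {
    if (any(width(sites) != 1L))
      stop("site calls must have width 1")
    if (any(start(sites) < 1L))
      stop("positions must be >= 1")
    if (any(!as.character(strand(sites)) %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    if (any(sites$n_meth < 0L) || any(sites$n_unmeth < 0L))
      stop("counts must be non-negative")
    tri <- sites$trinucleotide
    bad <- !is.na(tri) & nchar(tri) == 3L & substr(tri, 2L, 2L) != "C"
    if (any(bad))
      stop("trinucleotide middle base must be C (first offender: ",
           tri[which(bad)[1L]], ")")
  }
  invisible(TRUE)
}

.parseIntStrict <- function(x, what, lines) {
  ok <- grepl("^[0-9]+$", x)
  if (!all(ok))
    stop("non-integer ", what, " at line ", lines[which(!ok)[1L]],
         ": '", x[which(!ok)[1L]], "'")
  as.integer(x)
}

#' Read a Bismark-style cytosine report
#'
#' Parses the tab-separated per-cytosine report produced by Bismark's
#' coverage2cytosine (columns: chromosome, 1-based position, strand,
#' methylated count, unmethylated count, context class, trinucleotide).
#' Zero-coverage lines are retained; downstream quantification filters on
#' total coverage. The 6-column "coverage" dialect (chromosome, start, end,
#' percentage, methylated, unmethylated) is supported when a genome is
#' supplied from which context can be derived.
#'
#' @param path file path.
#' @param dialect "cytosine" (7 columns, default) or "coverage" (6 columns).
#' @param genome DNAStringSet; required for the coverage dialect.
#' @return GRanges of site calls (see \code{\link{validateSiteCalls}}).
#' @export
readCytosineReport <- function(path, dialect = c("cytosine", "coverage"),
                               genome = NULL) {
  dialect <- match.arg(dialect)
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (!length(raw)) return(.emptySiteCalls())
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  want <- if (dialect == "cytosine") 7L else 6L
  if (any(nf != want))
    stop("expected ", want, " tab-separated columns but found ",
         nf[which(nf != want)[1L]], " at line ", which(nf != want)[1L])
  m <- matrix(unlist(fields), ncol = want, byrow = TRUE)
  lines <- seq_len(nrow(m))
  if (dialect == "cytosine") {
    strand <- m[, 3L]
    if (any(!strand %in% c("+", "-")))
      stop("unknown strand symbol '",
           strand[which(!strand %in% c("+", "-"))[1L]], "' at line ",
           lines[which(!strand %in% c("+", "-"))[1L]])
    gr <- GRanges(m[, 1L],
                  IRanges(.parseIntStrict(m[, 2L], "position", lines),
                          width = 1L),
                  strand = strand,
                  n_meth = .parseIntStrict(m[, 4L], "methylated count", lines),
                  n_unmeth = .parseIntStrict(m[, 5L], "unmethylated count",
                                             lines),
                  context = m[, 6L],
                  trinucleotide = m[, 7L])
  } else {
    if (is.null(genome))
      stop("the coverage dialect carries no context; supply a genome")
    pos <- .parseIntStrict(m[, 2L], "position", lines)
    gr <- GRanges(m[, 1L], IRanges(pos, width = 1L), strand = "+",
                  n_meth = .parseIntStrict(m[, 5L], "methylated count", lines),
                  n_unmeth = .parseIntStrict(m[, 6L], "unmethylated count",
                                             lines),
                  context = NA_character_,
                  trinucleotide = NA_character_)
    gr <- .deriveContext(gr, genome)
  }
  validateSiteCalls(gr)
  gr
}

.emptySiteCalls <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(n_meth = integer(), n_unmeth = integer(),
                         context = character(),
                         trinucleotide = character())
  gr
}

#' Write site calls as a Bismark-style cytosine report
#'
#' Records are sorted by (chromosome, position, strand) on output so the
#' file layout is canonical regardless of input order; the read/write pair
#' is an exact round trip.
#'
#' @param sites GRanges of site calls.
#' @param path output path.
#' @return Invisibly the path.
#' @export
writeCytosineReport <- function(sites, path) {
  validateSiteCalls(sites)
  o <- order(as.character(seqnames(sites)), start(sites),
             as.character(strand(sites)))
  sites <- sites[o]
  df <- data.frame(
    chrom = as.character(seqnames(sites)),
    pos = start(sites),
    strand = as.character(strand(sites)),
    n_meth = sites$n_meth,
    n_unmeth = sites$n_unmeth,
    context = sites$context,
    trinucleotide = sites$trinucleotide,
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genomic features from a BED file
#'
#' BED coordinates (0-based, half-open) are converted to the package's
#' 1-based inclusive convention. Records with zero or negative width are
#' rejected with a warning reporting the number of rejects. A missing name
#' column yields auto-generated ids \code{feat_1..feat_k}.
#'
#' @param path BED3+ file.
#' @param contextClass label attached to every feature (e.g. "promoter").
#' @return GRanges with metadata columns \code{feature_id} and
#'   \code{context_class}.
#' @export
readFeaturesBed <- function(path, contextClass = "feature") {
  gr <- rtracklayer::import(path, format = "BED")
  drop <- width(gr) < 1L
  if (any(drop)) {
    warning(sum(drop), " feature(s) with start >= end rejected")
    gr <- gr[!drop]
  }
  ids <- if (!is.null(gr$name) && !all(is.na(gr$name))) as.character(gr$name)
         else paste0("feat_", seq_along(gr))
  mcols(gr) <- DataFrame(feature_id = ids,
                         context_class = rep(contextClass, length(gr)))
  gr
}

#' Write genomic features to a BED file
#'
#' Converts 1-based inclusive coordinates back to BED's 0-based half-open
#' convention; \code{readFeaturesBed(writeFeaturesBed(x))} round-trips
#' coordinates and ids exactly.
#'
#' @param features GRanges with a \code{feature_id} column.
#' @param path output path.
#' @return Invisibly the path.
#' @export
writeFeaturesBed <- function(features, path) {
  df <- data.frame(
    chrom = as.character(seqnames(features)),
    start = start(features) - 1L,
    end = end(features),
    name = features$feature_id,
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genes x cells expression count table
#'
#' @param path TSV with a header row of cell ids; first column gene ids.
#' @return integer matrix, genes x cells.
#' @export
readExpressionCounts <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected gene ids plus at least one cell column")
  genes <- as.character(df[[1L]])
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in count table")
  if (any(is.na(m))) stop("missing values in count table")
  if (any(m < 0)) stop("negative counts are not allowed")
  if (any(m != round(m))) stop("counts must be integers")
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  if (anyDuplicated(colnames(m)))
    stop("duplicated cell ids in header")
  m
}

#' Write a genes x cells expression count table
#'
#' @param counts integer matrix with gene row names and cell column names.
#' @param path output path.
#' @return Invisibly the path.
#' @export
writeExpressionCounts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
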