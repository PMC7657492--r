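#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   strand<- findOverlaps countOverlaps mcols mcols<- GRangesList
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors DataFrame queryHits subjectHits Rle
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assays<-
#'   rowRanges rowData rowData<- colData colData<-
NULL

VALID_MUSCLES <- c("EOM", "TA")
VALID_GRAFTS  <- c("pre", "post")
ELEMENT_CLASSES <- c("promoter", "enhancer", "gene_body", "cgi", "repeat",
                     "hox_window")

#' Per-sample CpG methylation calls
#'
#' Holds one sample's CpG-level bisulfite calls as width-1 genomic positions
#' with methylated / unmethylated read counts. Positions are 1-based, as in
#' Bismark coverage output; every stored site carries at least one read.
#'
#' @slot sampleId single sample identifier.
#' @slot calls a width-1 \link[GenomicRanges]{GRanges} with integer metadata
#'   columns \code{nMeth} and \code{nUnmeth}.
#' @export
setClass("CpGCallSet",
         slots = c(sampleId = "character", calls = "GRanges"))

setValidity("CpGCallSet", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-NA string")
  cl <- object@calls
  if (!all(c("nMeth", "nUnmeth") %in% colnames(mcols(cl))))
    msg <- c(msg, "calls must carry nMeth and nUnmeth metadata columns")
  else {
    nm <- mcols(cl)$nMeth; nu <- mcols(cl)$nUnmeth
    if (any(width(cl) != 1L))
      msg <- c(msg, "CpG calls must be width-1 positions")
    if (any(nm < 0L) || any(nu < 0L))
      msg <- c(msg, "counts must be non-negative")
    if (any(nm + nu < 1L))
      msg <- c(msg, "every stored CpG must have >= 1 read")
    key <- paste(as.character(seqnames(cl)), start(cl))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (chrom, position) in calls")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CpGCallSet
#'
#' @param sampleId sample identifier.
#' @param chrom,pos chromosome names and 1-based CpG positions.
#' @param nMeth,nUnmeth methylated / unmethylated read counts.
#' @return a \linkS4class{CpGCallSet}.
#' @examples
#' CpGCallSet("s1", "chr1", c(100, 200), nMeth = c(2, 0), nUnmeth = c(2, 4))
#' @export
CpGCallSet <- function(sampleId, chrom, pos, nMeth, nUnmeth) {
  gr <- GRanges(chrom, IRanges(pos, width = 1L))
  mcols(gr)$nMeth <- as.integer(nMeth)
  mcols(gr)$nUnmeth <- as.integer(nUnmeth)
  gr <- sort(gr)
  new("CpGCallSet", sampleId = as.character(sampleId), calls = gr)
}

#' @describeIn CpGCallSet-class number of CpG sites
#' @param x,object a \code{CpGCallSet}
#' @export
setMethod("length", "CpGCallSet", function(x) length(x@calls))

#' @describeIn CpGCallSet-class sample identifier accessor
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname CpGCallSet-class
#' @export
setMethod("sampleId", "CpGCallSet", function(object) object@sampleId)

#' @describeIn CpGCallSet-class the underlying calls GRanges
#' @export
setGeneric("cpgCalls", function(object) standardGeneric("cpgCalls"))

#' @rdname CpGCallSet-class
#' @export
setMethod("cpgCalls", "CpGCallSet", function(object) object@calls)

#' Per-site methylation ratios of a call set
#'
#' @param object a \linkS4class{CpGCallSet}.
#' @return numeric vector of per-site percentages 100 * nMeth / depth.
#' @export
setGeneric("siteRatios", function(object) standardGeneric("siteRatios"))

#' @rdname siteRatios
#' @export
setMethod("siteRatios", "CpGCallSet", function(object) {
  m <- mcols(object@calls)
  100 * m$nMeth / (m$nMeth + m$nUnmeth)
})

setMethod("show", "CpGCallSet", function(object) {
  m <- mcols(object@calls)
  cat("CpGCallSet for sample", object@sampleId, "with",
      length(object@calls), "CpG sites\n")
  cat("  mean depth:",
      round(mean(m$nMeth + m$nUnmeth), 2),
      " mean methylation:", round(mean(siteRatios(object)), 2), "%\n")
})

# ---------------------------------------------------------------------------

#' Element x sample methylation container
#'
#' A \link[SummarizedExperiment]{RangedSummarizedExperiment} subclass with
#' assays \code{meth} (mean methylation percent, \code{NA} where an element
#' failed the coverage filter) and \code{nCpGs} (covered CpG count behind
#' each value). Row ranges are annotated elements (column
#' \code{elementClass}); column data is the sample sheet.
#'
#' @export
setClass("MethylationExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("MethylationExperiment", function(object) {
  msg <- character()
  if (!all(c("meth", "nCpGs") %in% names(assays(object))))
    return("assays 'meth' and 'nCpGs' are required")
  v <- assay(object, "meth")
  if (any(v < 0 | v > 100, na.rm = TRUE))
    msg <- c(msg, "methylation values must lie in [0, 100]")
  if (!all(c("sample_id", "muscle", "graft") %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain the sample sheet")
  if (length(msg)) msg else TRUE
})

#' Construct a MethylationExperiment from matrices
#'
#' Lower-level constructor for pre-computed matrices; most users build the
#' object from calls with \code{\link{methylationExperiment}}.
#'
#' @param meth element x sample percent matrix (NA = not quantified).
#' @param sheet sample sheet (columns must match the matrix columns).
#' @param elements element GRanges (rows); defaults to unit ranges on a
#'   placeholder chromosome, for matrix-only workflows.
#' @param nCpGs covered-CpG count matrix; defaults to 0 where meth is NA
#'   and \code{min_cpgs} elsewhere.
#' @param min_cpgs value used for the default nCpGs fill.
#' @return a \linkS4class{MethylationExperiment}.
#' @export
MethylationExperiment <- function(meth, sheet, elements = NULL, nCpGs = NULL,
                                  min_cpgs = 2) {
  validateSampleSheet(sheet)
  meth <- meth[, sheet$sample_id, drop = FALSE]
  if (is.null(elements)) {
    elements <- GRanges("unplaced", IRanges(seq_len(nrow(meth)), width = 1L))
    names(elements) <- rownames(meth)
    mcols(elements)$elementClass <- "enhancer"
  }
  if (is.null(nCpGs))
    nCpGs <- ifelse(is.na(meth), 0L, as.integer(min_cpgs))  # keeps dims
  se <- SummarizedExperiment(assays = list(meth = meth, nCpGs = nCpGs),
                             rowRanges = elements,
                             colData = DataFrame(sheet,
                                                 row.names = sheet$sample_id))
  new("MethylationExperiment", se)
}

#' @describeIn MethylationExperiment-class methylation percent matrix
#' @param object a \code{MethylationExperiment}
#' @export
setGeneric("methValues", function(object) standardGeneric("methValues"))

#' @rdname MethylationExperiment-class
#' @export
setMethod("methValues", "MethylationExperiment",
          function(object) assay(object, "meth"))

#' @describeIn MethylationExperiment-class covered-CpG count matrix
#' @export
setGeneric("cpgCounts", function(object) standardGeneric("cpgCounts"))

#' @rdname MethylationExperiment-class
#' @export
setMethod("cpgCounts", "MethylationExperiment",
          function(object) assay(object, "nCpGs"))

setMethod("show", "MethylationExperiment", function(object) {
  v <- assay(object, "meth")
  cat("MethylationExperiment:", nrow(object), "elements x", ncol(object),
      "samples\n")
  cl <- rowRanges(object)$elementClass
  if (!is.null(cl)) {
    tab <- table(cl)
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  cat("  quantified values:", sum(!is.na(v)), "/", length(v), "\n")
})

# ---------------------------------------------------------------------------

#' Gene x sample expression container
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} subclass with assays
#' \code{counts} (raw non-negative integers) and \code{log2rpm}
#' (log2(1e6 * count / librarySize + 1)); column data is the sample sheet,
#' row data the gene table (chrom, strand, tss, optional hox_cluster).
#'
#' @export
setClass("ExpressionExperiment", contains = "SummarizedExperiment")

setValidity("ExpressionExperiment", function(object) {
  msg <- character()
  if (!all(c("counts", "log2rpm") %in% names(assays(object))))
    return("assays 'counts' and 'log2rpm' are required")
  cnt <- assay(object, "counts")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    msg <- c(msg, "counts must be non-negative integers")
  if (!all(c("sample_id", "muscle", "graft") %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain the sample sheet")
  if (length(msg)) msg else TRUE
})

#' @describeIn ExpressionExperiment-class log2 RPM matrix accessor
#' @param object an \code{ExpressionExperiment}
#' @export
setGeneric("log2rpm", function(object) standardGeneric("log2rpm"))

#' @rdname ExpressionExperiment-class
#' @export
setMethod("log2rpm", "ExpressionExperiment",
          function(object) assay(object, "log2rpm"))

#' @describeIn ExpressionExperiment-class raw count matrix accessor
#' @export
setGeneric("rawCounts", function(object) standardGeneric("rawCounts"))

#' @rdname ExpressionExperiment-class
#' @export
setMethod("rawCounts", "ExpressionExperiment",
          function(object) assay(object, "counts"))

setMethod("show", "ExpressionExperiment", function(object) {
  cat("ExpressionExperiment:", nrow(object), "genes x", ncol(object),
      "samples\n")
  grp <- table(sampleGroups(as.data.frame(colData(object))))
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
})

#' Sample sheet accessor
#'
#' @param object a \code{MethylationExperiment} or \code{ExpressionExperiment}.
#' @return the sample sheet as a data.frame.
#' @export
setGeneric("sampleSheet", function(object) standardGeneric("sampleSheet"))

#' @rdname sampleSheet
#' @export
setMethod("sampleSheet", "SummarizedExperiment", function(object) {
  as.data.frame(colData(object))
})
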