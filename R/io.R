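#' @importFrom data.table fread fwrite
NULL

# fread wrapper: tab-separated text, gzip handled via base gzfile() so no
# extra decompression dependency is needed
freadTsv <- function(path, header = FALSE, colClasses = NULL) {
  args <- list(sep = "\t", header = header, data.table = FALSE,
               fill = TRUE, na.strings = "NA", showProgress = FALSE)
  if (!is.null(colClasses)) args$colClasses <- colClasses
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    args$text <- readLines(con)
  } else {
    args$file <- path
  }
  do.call(fread, args)
}

#' Read a BED3/BED6 file into a GRanges
#'
#' BED coordinates (0-based half-open) are converted to the package's
#' internal 1-based closed GRanges convention here and only here; every
#' writer converts back. Strand is taken from column 6 when present,
#' defaulting to \code{"*"}. Gzipped input is read transparently.
#'
#' @param path BED file (3+ tab-separated columns).
#' @return a \link[GenomicRanges]{GRanges}; column 4, when present, becomes
#'   the range names.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200", bed)
#' readBed(bed)
#' @export
readBed <- function(path) {
  d <- freadTsv(path)
  if (ncol(d) < 3L)
    stop("BED file must have >= 3 tab-separated columns: ", path)
  start0 <- suppressWarnings(as.numeric(d[[2L]]))
  end0 <- suppressWarnings(as.numeric(d[[3L]]))
  bad <- which(is.na(d[[1L]]) | d[[1L]] == "" | is.na(start0) | is.na(end0))
  if (length(bad))
    stop("malformed BED line ", bad[1L], " in ", path)
  bad <- which(end0 <= start0 | start0 < 0)
  if (length(bad))
    stop("invalid interval (end <= start or negative start) at BED line ",
         bad[1L], " in ", path)
  strand <- if (ncol(d) >= 6L) {
    s <- as.character(d[[6L]])
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  gr <- GRanges(d[[1L]], IRanges(start0 + 1L, end0), strand = strand)
  if (ncol(d) >= 4L && !all(is.na(d[[4L]]))) names(gr) <- as.character(d[[4L]])
  gr
}

#' Write a GRanges as BED
#'
#' @param gr a GRanges; names become column 4, any \code{score} metadata
#'   column becomes column 5, strand column 6 (\code{"*"} written as ".").
#' @param path output file; a \code{.gz} suffix gzips the output.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(gr, path) {
  nm <- if (is.null(names(gr))) rep(".", length(gr)) else names(gr)
  sc <- if ("score" %in% colnames(mcols(gr))) mcols(gr)$score else
    rep(0, length(gr))
  st <- as.character(strand(gr))
  st[st == "*"] <- "."
  d <- data.frame(chrom = as.character(seqnames(gr)),
                  start = start(gr) - 1L, end = end(gr),
                  name = nm, score = sc, strand = st)
  fwrite(d, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Bismark-style coverage file into a CpGCallSet
#'
#' Expected columns: chrom, start, end, percent methylation, count
#' methylated, count unmethylated, with start == end giving the 1-based CpG
#' position. The percent column is ignored in favour of the counts (and
#' recomputed on write); a discrepancy above 0.5 points triggers a warning.
#' Zero-coverage records are dropped with a warning.
#'
#' @param path coverage file (optionally gzipped).
#' @param sampleId sample identifier; defaults to the file's base name.
#' @return a \linkS4class{CpGCallSet}.
#' @export
readCoverage <- function(path, sampleId = sub("\\.(cov|txt|tsv)(\\.gz)?$", "",
                                              basename(path))) {
  d <- freadTsv(path)
  if (ncol(d) < 6L)
    stop("coverage file must have 6 tab-separated columns: ", path)
  pos <- suppressWarnings(as.numeric(d[[2L]]))
  end <- suppressWarnings(as.numeric(d[[3L]]))
  nm <- suppressWarnings(as.numeric(d[[5L]]))
  nu <- suppressWarnings(as.numeric(d[[6L]]))
  bad <- which(is.na(pos) | is.na(end) | is.na(nm) | is.na(nu))
  if (length(bad))
    stop("malformed coverage line ", bad[1L], " in ", path)
  if (any(pos != end))
    stop("coverage line ", which(pos != end)[1L],
         ": start != end (expected single 1-based positions) in ", path)
  if (any(nm < 0 | nu < 0))
    stop("negative counts at coverage line ", which(nm < 0 | nu < 0)[1L])
  depth <- nm + nu
  zero <- depth == 0
  if (any(zero)) {
    warning(sum(zero), " zero-coverage record(s) dropped from ", path)
    d <- d[!zero, , drop = FALSE]
    pos <- pos[!zero]; nm <- nm[!zero]; nu <- nu[!zero]; depth <- depth[!zero]
  }
  pct <- suppressWarnings(as.numeric(d[[4L]]))
  off <- which(!is.na(pct) & abs(pct - 100 * nm / depth) > 0.5)
  if (length(off))
    warning(length(off), " record(s) with % methylation inconsistent with ",
            "counts by > 0.5 in ", path, " (counts kept)")
  CpGCallSet(sampleId, d[[1L]], pos, nm, nu)
}

#' Write a CpGCallSet as a Bismark-style coverage file
#'
#' The percent column is recomputed as 100 * nMeth / (nMeth + nUnmeth).
#'
#' @param object a \linkS4class{CpGCallSet}.
#' @param path output file; \code{.gz} suffix gzips.
#' @return \code{path}, invisibly.
#' @export
writeCoverage <- function(object, path) {
  cl <- cpgCalls(object)
  m <- mcols(cl)
  d <- data.frame(chrom = as.character(seqnames(cl)),
                  start = start(cl), end = start(cl),
                  pct = 100 * m$nMeth / (m$nMeth + m$nUnmeth),
                  nMeth = m$nMeth, nUnmeth = m$nUnmeth)
  fwrite(d, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene read-count matrix
#'
#' @param path TSV with a \code{gene_id} column plus one column per sample.
#' @param sheet sample sheet (see \code{\link{readSampleSheet}}); sample
#'   order of the result follows the sheet.
#' @return integer matrix, genes x samples.
#' @export
readCounts <- function(path, sheet) {
  validateSampleSheet(sheet)
  d <- freadTsv(path, header = TRUE)
  if (!"gene_id" %in% colnames(d))
    stop("counts table must have a gene_id column: ", path)
  miss <- setdiff(sheet$sample_id, colnames(d))
  if (length(miss))
    stop("sample(s) in sheet missing from counts table: ",
         paste(miss, collapse = ", "))
  dup <- d$gene_id[duplicated(d$gene_id)]
  if (length(dup))
    stop("duplicate gene_id in counts table: ",
         paste(unique(dup), collapse = ", "))
  m <- as.matrix(d[, sheet$sample_id, drop = FALSE])
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers (offending gene: ",
         d$gene_id[which(rowSums(is.na(m) | m < 0 | m != round(m)) > 0)[1L]],
         ")")
  storage.mode(m) <- "integer"
  rownames(m) <- d$gene_id
  m
}

#' Read a gene table
#'
#' @param path TSV with columns gene_id, chrom, strand, tss and optionally
#'   hox_cluster.
#' @return data.frame, one row per gene.
#' @export
readGeneTable <- function(path) {
  d <- freadTsv(path, header = TRUE)
  need <- c("gene_id", "chrom", "strand", "tss")
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    stop("gene table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$gene_id))
    stop("duplicate gene_id in gene table")
  if (!all(d$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (!"hox_cluster" %in% colnames(d)) d$hox_cluster <- NA_character_
  d
}

#' Read a sample sheet
#'
#' @param path TSV with columns sample_id, muscle, graft, donor_id.
#' @return validated data.frame.
#' @export
readSampleSheet <- function(path) {
  d <- freadTsv(path, header = TRUE, colClasses = "character")
  validateSampleSheet(d)
  d
}

#' Export annotated elements as BED6+
#'
#' Extra columns: elementClass, gene_id, distance_to_tss, cgi_overlap.
#'
#' @param elements annotated element GRanges (see the annotation functions).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
exportElements <- function(elements, path) {
  mc <- mcols(elements)
  g <- function(col, default) if (col %in% colnames(mc)) mc[[col]] else default
  st <- as.character(strand(elements))
  st[st == "*"] <- "."
  d <- data.frame(
    chrom = as.character(seqnames(elements)),
    start = start(elements) - 1L, end = end(elements),
    name = if (is.null(names(elements))) rep(".", length(elements))
           else names(elements),
    score = 0, strand = st,
    element_class = g("elementClass", NA_character_),
    gene_id = g("gene_id", NA_character_),
    distance_to_tss = g("distance_to_tss", NA_real_),
    cgi_overlap = g("cgi_overlap", NA))
  fwrite(d, path, sep = "\t", col.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a numeric matrix as TSV with 'NA' missing marker
#'
#' @param m matrix with row names.
#' @param path output file.
#' @param id_col name for the row-identifier column.
#' @return \code{path}, invisibly.
#' @export
writeMatrixTsv <- function(m, path, id_col = "id") {
  d <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(d)[1L] <- id_col
  fwrite(d, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
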