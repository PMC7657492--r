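HOX_CLUSTERS <- c("HoxA", "HoxB", "HoxC", "HoxD")

#' Define promoter elements around gene TSSs
#'
#' A promoter spans \code{upstream} bp upstream to \code{downstream} bp
#' downstream of the TSS in transcription orientation (default -2000/+500),
#' clipped at the chromosome origin. Strand is required because the span is
#' asymmetric.
#'
#' @param genes gene table (data.frame with gene_id, chrom, strand, tss;
#'   tss is a 1-based position).
#' @param upstream,downstream extent in bp.
#' @return GRanges named by gene_id with metadata columns
#'   \code{elementClass = "promoter"}, \code{gene_id} and
#'   \code{distance_to_tss = 0}.
#' @examples
#' genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
#'                     tss = 10000)
#' makePromoters(genes)  # chr1:8001-10500
#' @export
makePromoters <- function(genes, upstream = 2000, downstream = 500) {
  if (any(is.na(genes$strand)) || !all(genes$strand %in% c("+", "-")))
    stop("every gene needs strand '+' or '-' to orient its promoter")
  plus <- genes$strand == "+"
  start1 <- ifelse(plus, genes$tss - upstream + 1L, genes$tss - downstream + 1L)
  end1 <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  start1 <- pmax(start1, 1L)
  gr <- GRanges(genes$chrom, IRanges(start1, end1), strand = genes$strand)
  names(gr) <- genes$gene_id
  mcols(gr)$elementClass <- "promoter"
  mcols(gr)$gene_id <- genes$gene_id
  mcols(gr)$distance_to_tss <- 0
  gr
}

#' Split promoters into CGI and non-CGI promoters
#'
#' A promoter is a CGI promoter when it shares at least one bp with a CpG
#' island. The split is an exhaustive, disjoint partition.
#'
#' @param promoters promoter GRanges from \code{\link{makePromoters}}.
#' @param cgis CpG-island GRanges.
#' @return list with elements \code{cgi_promoters} and
#'   \code{non_cgi_promoters}; both carry a logical \code{cgi_overlap}
#'   metadata column.
#' @export
splitPromotersByCgi <- function(promoters, cgis) {
  hit <- overlapsAny(promoters, cgis, ignore.strand = TRUE)
  mcols(promoters)$cgi_overlap <- hit
  list(cgi_promoters = promoters[hit],
       non_cgi_promoters = promoters[!hit])
}

#' Define enhancers from H3K27ac peaks
#'
#' Enhancers are H3K27ac peaks that do not overlap any promoter; a peak
#' overlapping a promoter by even one bp is excluded entirely (no trimming).
#' The resulting set is checked to be promoter-free on every call.
#'
#' @param peaks H3K27ac peak GRanges.
#' @param promoters promoter GRanges.
#' @return GRanges of enhancer elements (\code{elementClass = "enhancer"});
#'   unnamed peaks are given ids \code{enh_00001, ...}.
#' @export
defineEnhancers <- function(peaks, promoters) {
  keep <- !overlapsAny(peaks, promoters, ignore.strand = TRUE)
  enh <- granges(peaks[keep], use.mcols = FALSE)
  strand(enh) <- "*"
  if (is.null(names(enh)) || anyNA(names(enh)) || anyDuplicated(names(enh)))
    names(enh) <- sprintf("enh_%05d", seq_along(enh))
  mcols(enh)$elementClass <- "enhancer"
  # the defining property, revalidated on every run
  stopifnot(sum(countOverlaps(enh, promoters, ignore.strand = TRUE)) == 0L)
  enh
}

# per-chromosome nearest-TSS lookup used by linkEnhancersToGenes
.nearestTss <- function(mid, tss, gene_id) {
  o <- order(tss, gene_id)
  ts <- tss[o]; gid <- gene_id[o]
  # collapse duplicate TSS positions to their lexicographically smallest gene
  first <- !duplicated(ts)
  tu <- ts[first]
  gBest <- vapply(split(gid, match(ts, tu)), min, character(1L))
  i <- findInterval(mid, tu)
  n <- length(tu)
  dl <- ifelse(i >= 1L, mid - tu[pmax(i, 1L)], Inf)
  dr <- ifelse(i < n, tu[pmin(i + 1L, n)] - mid, Inf)
  gl <- gBest[pmax(i, 1L)]
  gr_ <- gBest[pmin(i + 1L, n)]
  d <- pmin(dl, dr)
  g <- ifelse(dl < dr, gl, ifelse(dr < dl, gr_, pmin(gl, gr_)))
  list(gene_id = g, distance = d)
}

#' Link enhancers to their nearest gene
#'
#' Each enhancer is assigned the gene whose TSS is closest to the enhancer
#' midpoint; enhancers farther than \code{max_distance} (default 1 Mb) from
#' any TSS are left unlinked. Ties are broken by lexicographically smallest
#' gene_id; chromosomes with no genes yield unlinked enhancers.
#'
#' @param enhancers enhancer GRanges from \code{\link{defineEnhancers}}.
#' @param genes gene table.
#' @param max_distance maximum midpoint-to-TSS distance in bp.
#' @return the enhancers with metadata columns \code{gene_id} and
#'   \code{distance_to_tss} (both NA when unlinked).
#' @export
linkEnhancersToGenes <- function(enhancers, genes, max_distance = 1e6) {
  mid <- floor((start(enhancers) + end(enhancers)) / 2)
  chrom <- as.character(seqnames(enhancers))
  gene_id <- rep(NA_character_, length(enhancers))
  dist <- rep(NA_real_, length(enhancers))
  for (ch in unique(chrom)) {
    gsel <- genes$chrom == ch
    if (!any(gsel)) next
    esel <- which(chrom == ch)
    hit <- .nearestTss(mid[esel], genes$tss[gsel], genes$gene_id[gsel])
    ok <- hit$distance <= max_distance
    gene_id[esel[ok]] <- hit$gene_id[ok]
    dist[esel[ok]] <- hit$distance[ok]
  }
  mcols(enhancers)$gene_id <- gene_id
  mcols(enhancers)$distance_to_tss <- dist
  enhancers
}

#' Tile a Hox cluster with fixed-width windows
#'
#' Windows tile the span from (min TSS - flank) to (max TSS + flank) over
#' the genes labelled with the requested cluster.
#'
#' @param genes gene table with a \code{hox_cluster} column.
#' @param cluster one of "HoxA", "HoxB", "HoxC", "HoxD".
#' @param window window width in bp (default 1 kb).
#' @param flank flank beyond the outermost TSSs in bp (default 5 kb).
#' @return GRanges of \code{hox_window} elements named
#'   \code{<cluster>_w0001, ...}.
#' @export
makeHoxWindows <- function(genes, cluster, window = 1000, flank = 5000) {
  if (!cluster %in% HOX_CLUSTERS)
    stop("unknown Hox cluster label: ", cluster)
  sel <- !is.na(genes$hox_cluster) & genes$hox_cluster == cluster
  if (!any(sel))
    stop("no gene carries hox_cluster label ", cluster)
  g <- genes[sel, ]
  if (length(unique(g$chrom)) != 1L)
    stop("genes of cluster ", cluster, " lie on multiple chromosomes")
  lo <- max(1L, min(g$tss) - flank)
  hi <- max(g$tss) + flank
  span <- hi - lo          # half-open span, so 50 kb tiles into 50 windows
  n <- max(1L, ceiling(span / window))
  starts <- lo + (seq_len(n) - 1L) * window
  ends <- pmin(starts + window - 1L, hi - 1L)
  gr <- GRanges(g$chrom[1L], IRanges(starts, ends))
  names(gr) <- sprintf("%s_w%04d", cluster, seq_len(n))
  mcols(gr)$elementClass <- "hox_window"
  mcols(gr)$hox_cluster <- cluster
  gr
}
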