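#' Library-size normalisation to log2 RPM
#'
#' value = log2(1e6 * count / librarySize + 1), where librarySize is the
#' sample's total count. The +1 pseudocount (in RPM units) keeps zeros at
#' zero and is zero-safe.
#'
#' @param counts genes x samples matrix of non-negative integers.
#' @return matrix of log2 RPM values with the same dimnames.
#' @examples
#' normalizeLog2Rpm(matrix(c(0, 1e6), 2, dimnames = list(c("a", "b"), "s1")))
#' @export
normalizeLog2Rpm <- function(counts) {
  L <- colSums(counts)
  if (any(L == 0)) stop("zero library size in sample(s): ",
                        paste(colnames(counts)[L == 0], collapse = ", "))
  log2(sweep(counts, 2L, 1e6 / L, `*`) + 1)
}

#' Build an ExpressionExperiment from counts and a sample sheet
#'
#' @param counts genes x samples integer matrix (column order need not
#'   match the sheet; it is reordered).
#' @param sheet sample sheet.
#' @param genes optional gene table; rows matching rownames(counts) by
#'   gene_id become rowData.
#' @return an \linkS4class{ExpressionExperiment} with assays \code{counts}
#'   and \code{log2rpm}.
#' @export
expressionExperiment <- function(counts, sheet, genes = NULL) {
  validateSampleSheet(sheet)
  miss <- setdiff(sheet$sample_id, colnames(counts))
  if (length(miss))
    stop("counts lack column(s): ", paste(miss, collapse = ", "))
  counts <- counts[, sheet$sample_id, drop = FALSE]
  rd <- if (!is.null(genes)) {
    DataFrame(genes[match(rownames(counts), genes$gene_id), , drop = FALSE],
              row.names = rownames(counts))
  } else DataFrame(row.names = rownames(counts))
  se <- SummarizedExperiment(
    assays = list(counts = counts, log2rpm = normalizeLog2Rpm(counts)),
    rowData = rd,
    colData = DataFrame(sheet, row.names = sheet$sample_id))
  new("ExpressionExperiment", se)
}

# vectorized Welch two-sample t on rows of a matrix
.welchRows <- function(x, colsA, colsB) {
  na <- length(colsA); nb <- length(colsB)
  ma <- rowMeans(x[, colsA, drop = FALSE])
  mb <- rowMeans(x[, colsB, drop = FALSE])
  va <- apply(x[, colsA, drop = FALSE], 1L, stats::var)
  vb <- apply(x[, colsB, drop = FALSE], 1L, stats::var)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate dispersion: no variance in either group
  flat <- se2 == 0
  p[flat] <- ifelse(ma[flat] == mb[flat], 1, 0)
  t[flat] <- ifelse(ma[flat] == mb[flat], 0, Inf * sign((ma - mb)[flat]))
  list(mean_a = ma, mean_b = mb, t = t, p = p)
}

#' Location differential expression (Welch's t on log2 RPM)
#'
#' log2 fold change is mean log2 RPM of group A minus group B; a gene is a
#' DEG when |log2fc| exceeds log2(fc_threshold) and p < alpha, with
#' specificity assigned by sign (positive toward group A's muscle).
#' p-values are not adjusted for the DEG call (the published criterion);
#' BH-adjusted values are reported alongside.
#'
#' @param object an \linkS4class{ExpressionExperiment}.
#' @param groupA,groupB group labels (defaults "EOM-pre" vs "TA-pre").
#' @param fc_threshold fold-change threshold on the linear scale
#'   (default 2).
#' @param alpha p-value threshold (default 0.05).
#' @return data.frame: gene_id, log2fc, p, padj, specificity
#'   (\code{"EOM"}, \code{"TA"} or \code{"none"}).
#' @export
differentialExpression <- function(object, groupA = "EOM-pre",
                                   groupB = "TA-pre", fc_threshold = 2,
                                   alpha = 0.05) {
  sheet <- sampleSheet(object)
  glab <- sampleGroups(sheet)
  colsA <- which(glab == groupA); colsB <- which(glab == groupB)
  if (length(colsA) < 3 || length(colsB) < 3)
    stop("each group needs >= 3 samples")
  x <- log2rpm(object)
  w <- .welchRows(x, colsA, colsB)
  log2fc <- w$mean_a - w$mean_b
  muscleA <- sub("-.*", "", groupA)
  muscleB <- sub("-.*", "", groupB)
  hit <- abs(log2fc) > log2(fc_threshold) & w$p < alpha
  data.frame(gene_id = rownames(x), log2fc = log2fc, p = w$p,
             padj = stats::p.adjust(w$p, "BH"),
             specificity = ifelse(hit, ifelse(log2fc > 0, muscleA, muscleB),
                                  "none"),
             row.names = NULL)
}

#' Remove the transplantation effect from post-graft transcriptomes
#'
#' Per gene, the expression change between TA MuSCs before and after
#' transplantation (mean log2 RPM TA-post minus TA-pre) is deducted from
#' every post-graft sample (TA-post and EOM-post); pre-graft samples are
#' untouched. The corrected TA-post per-gene means equal the TA-pre means
#' exactly.
#'
#' @param object an \linkS4class{ExpressionExperiment}.
#' @return the object with corrected \code{log2rpm}; the per-gene
#'   coefficient is stored in \code{rowData(object)$graft_delta}.
#' @export
correctExpression <- function(object) {
  sheet <- sampleSheet(object)
  glab <- sampleGroups(sheet)
  if (!any(glab == "TA-pre") || !any(glab == "TA-post"))
    stop("TA-pre and TA-post groups are required for the correction")
  x <- log2rpm(object)
  delta <- rowMeans(x[, glab == "TA-post", drop = FALSE]) -
    rowMeans(x[, glab == "TA-pre", drop = FALSE])
  post <- sheet$graft == "post"
  x[, post] <- x[, post] - delta
  assays(object)$log2rpm <- x
  rowData(object)$graft_delta <- delta
  object
}

#' Rescale post-graft expression of location-specific genes and classify
#' plasticity
#'
#' For each location-specific gene, pre-graft group means define a 0-100
#' scale: for a TA-specific gene 0 is the mean EOM-pre and 100 the mean
#' TA-pre expression (and symmetrically for EOM-specific genes). The mean
#' corrected expression of the post-graft group (default EOM-post) is
#' placed on that scale (scores are not clamped). A TA-specific gene is
#' resistant below 25, intermediate from 25 to 75 (boundaries inclusive)
#' and responsive above 75; for an EOM-specific gene responsive is below 25
#' and resistant above 75 — in both cases "responsive" means the gene
#' reached the host (TA-like) level.
#'
#' @param object a corrected \linkS4class{ExpressionExperiment} (see
#'   \code{\link{correctExpression}}).
#' @param degs DEG table from \code{\link{differentialExpression}}; only
#'   rows with specificity EOM or TA are used.
#' @param post_group post-graft group being classified
#'   (default "EOM-post").
#' @param lower,upper classification thresholds (defaults 25 and 75;
#'   boundary scores count as intermediate).
#' @return data.frame: gene_id, specificity, rescaled_score, category.
#' @export
rescaleAndClassify <- function(object, degs, post_group = "EOM-post",
                               lower = 25, upper = 75) {
  degs <- degs[degs$specificity %in% c("EOM", "TA"), , drop = FALSE]
  glab <- sampleGroups(sampleSheet(object))
  x <- log2rpm(object)
  idx <- match(degs$gene_id, rownames(x))
  if (anyNA(idx)) stop("DEG(s) absent from expression matrix")
  mE <- rowMeans(x[idx, glab == "EOM-pre", drop = FALSE])
  mT <- rowMeans(x[idx, glab == "TA-pre", drop = FALSE])
  xpost <- rowMeans(x[idx, glab == post_group, drop = FALSE])
  ta <- degs$specificity == "TA"
  denom <- ifelse(ta, mT - mE, mE - mT)
  zero <- denom == 0
  if (any(zero))
    warning(sum(zero), " gene(s) skipped: pre-graft group means equal")
  score <- ifelse(ta, 100 * (xpost - mE) / denom, 100 * (xpost - mT) / denom)
  category <- ifelse(score < lower,
                     ifelse(ta, "resistant", "responsive"),
                     ifelse(score > upper,
                            ifelse(ta, "responsive", "resistant"),
                            "intermediate"))
  out <- data.frame(gene_id = degs$gene_id, specificity = degs$specificity,
                    rescaled_score = score, category = category,
                    row.names = NULL)
  out[!zero, , drop = FALSE]
}

#' Category fractions of plasticity calls
#'
#' @param calls data.frame from \code{\link{rescaleAndClassify}}.
#' @return data.frame: specificity, category, n, fraction; fractions sum to
#'   1 within each specificity.
#' @export
plasticityFractions <- function(calls) {
  if (nrow(calls) == 0L) stop("no plasticity calls")
  cats <- c("responsive", "intermediate", "resistant")
  out <- do.call(rbind, lapply(split(calls, calls$specificity), function(d) {
    n <- vapply(cats, function(cc) sum(d$category == cc), integer(1L))
    data.frame(specificity = d$specificity[1L], category = cats, n = n,
               fraction = n / nrow(d))
  }))
  rownames(out) <- NULL
  out
}

#' Hox-cluster expression profile
#'
#' Per-gene group means of log2 RPM over the labelled Hox genes, ordered by
#' cluster and genomic position.
#'
#' @param object an \linkS4class{ExpressionExperiment} whose rowData
#'   carries \code{hox_cluster} and \code{tss}.
#' @param groups group labels to summarise (default: all present).
#' @return data.frame: gene_id, hox_cluster, chrom, tss, then one mean
#'   column per group.
#' @export
hoxExpressionProfile <- function(object,
                                 groups = unique(sampleGroups(sampleSheet(object)))) {
  rd <- as.data.frame(rowData(object))
  if (!"hox_cluster" %in% colnames(rd))
    stop("rowData lacks hox_cluster labels")
  sel <- which(!is.na(rd$hox_cluster))
  if (!length(sel)) stop("no gene carries a hox_cluster label")
  glab <- sampleGroups(sampleSheet(object))
  x <- log2rpm(object)[sel, , drop = FALSE]
  means <- vapply(groups, function(g)
    rowMeans(x[, glab == g, drop = FALSE]), numeric(length(sel)))
  out <- data.frame(gene_id = rownames(x), hox_cluster = rd$hox_cluster[sel],
                    chrom = rd$chrom[sel], tss = rd$tss[sel], means,
                    row.names = NULL, check.names = FALSE)
  out[order(out$hox_cluster, out$chrom, out$tss), , drop = FALSE]
}
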