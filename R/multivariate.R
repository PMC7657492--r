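#' Principal component analysis of a feature x sample matrix
#'
#' Features with any missing value (within the chosen subset) are dropped
#' with a message; features are centred across samples but not scaled (log2
#' RPM and percent methylation are already on meaningful common scales).
#' Component signs follow a deterministic convention: the largest-magnitude
#' loading of each component is positive.
#'
#' @param m features x samples numeric matrix.
#' @param feature_subset optional character vector of feature (row) names
#'   to restrict to.
#' @return list: \code{scores} (samples x components), \code{loadings}
#'   (features x components), \code{variance_fraction}, \code{n_features}.
#' @export
runPCA <- function(m, feature_subset = NULL) {
  if (!is.null(feature_subset))
    m <- m[intersect(feature_subset, rownames(m)), , drop = FALSE]
  if (ncol(m) < 2L) stop("PCA needs >= 2 samples")
  complete <- rowSums(is.na(m)) == 0L
  if (any(!complete))
    message(sum(!complete), " feature(s) with missing values dropped ",
            "before PCA")
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 2L) stop("fewer than 2 complete features")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2L, flip, `*`)
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  list(scores = scores, loadings = loadings,
       variance_fraction = pc$sdev^2 / sum(pc$sdev^2),
       n_features = nrow(m))
}

#' Mean silhouette width of groups along a score axis
#'
#' Convenience check of how well e.g. PC1 separates sample groups.
#'
#' @param values numeric vector (one value per sample).
#' @param labels group label per sample.
#' @return mean silhouette width in [-1, 1].
#' @export
groupSilhouette <- function(values, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(values))
  mean(sil[, "sil_width"])
}

#' Hierarchical clustering of sample correlation profiles
#'
#' Pairwise Pearson correlation of sample profiles (complete features
#' only), Euclidean distance between the samples' correlation vectors,
#' agglomerative clustering with average linkage.
#'
#' @param m features x samples matrix.
#' @return list: \code{hclust}, \code{correlation} (sample x sample),
#'   \code{order} (leaf order labels).
#' @export
correlationClustering <- function(m) {
  if (ncol(m) < 3L) stop("clustering needs >= 3 samples")
  complete <- rowSums(is.na(m)) == 0L
  m <- m[complete, , drop = FALSE]
  sdv <- apply(m, 2L, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(m)[sdv == 0], collapse = ", "))
  C <- stats::cor(m)
  hc <- stats::hclust(stats::dist(C), method = "average")
  list(hclust = hc, correlation = C, order = hc$labels[hc$order])
}

#' Write a dendrogram as Newick text
#'
#' @param hc an \code{hclust} object (e.g. from
#'   \code{\link{correlationClustering}}).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
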