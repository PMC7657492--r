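#' Mean methylation of elements for one sample
#'
#' Per element, the unweighted mean of per-site ratios
#' 100 * nMeth / (nMeth + nUnmeth) over covered CpGs inside the element;
#' missing (\code{NA}) when fewer than \code{min_cpgs} CpGs are covered.
#' The unweighted mean avoids read-depth bias between sites.
#'
#' @param calls a \linkS4class{CpGCallSet}.
#' @param elements element GRanges.
#' @param min_cpgs minimum covered CpGs for an element to be quantified
#'   (default 2).
#' @return data.frame with element_id, meth (percent or NA), n_cpgs.
#' @export
elementMethylation <- function(calls, elements, min_cpgs = 2) {
  gr <- cpgCalls(calls)
  ratios <- siteRatios(calls)
  ov <- findOverlaps(gr, elements, ignore.strand = TRUE)
  n <- length(elements)
  sums <- counts <- numeric(n)
  if (length(ov)) {
    s <- subjectHits(ov)
    agg <- rowsum(cbind(ratios[queryHits(ov)], 1), s)
    idx <- as.integer(rownames(agg))
    sums[idx] <- agg[, 1L]
    counts[idx] <- agg[, 2L]
  }
  meth <- ifelse(counts >= min_cpgs, sums / pmax(counts, 1), NA_real_)
  ids <- if (is.null(names(elements))) as.character(seq_len(n))
         else names(elements)
  data.frame(element_id = ids, meth = meth, n_cpgs = as.integer(counts))
}

#' Build a MethylationExperiment over samples
#'
#' Applies \code{\link{elementMethylation}} per sample and assembles the
#' element x sample percent matrix with its covered-CpG counts.
#'
#' @param callsList list of \linkS4class{CpGCallSet}, one per sample; list
#'   names or sampleIds must match the sheet's sample_id.
#' @param elements element GRanges.
#' @param sheet sample sheet.
#' @inheritParams elementMethylation
#' @return a \linkS4class{MethylationExperiment}.
#' @export
methylationExperiment <- function(callsList, elements, sheet, min_cpgs = 2) {
  validateSampleSheet(sheet)
  ids <- vapply(callsList, sampleId, character(1L))
  if (!all(sheet$sample_id %in% ids))
    stop("calls missing for sample(s): ",
         paste(setdiff(sheet$sample_id, ids), collapse = ", "))
  callsList <- callsList[match(sheet$sample_id, ids)]
  cols <- lapply(callsList, elementMethylation, elements = elements,
                 min_cpgs = min_cpgs)
  meth <- do.call(cbind, lapply(cols, `[[`, "meth"))
  ncp <- do.call(cbind, lapply(cols, `[[`, "n_cpgs"))
  dimnames(meth) <- dimnames(ncp) <- list(cols[[1L]]$element_id,
                                          sheet$sample_id)
  se <- SummarizedExperiment(assays = list(meth = meth, nCpGs = ncp),
                             rowRanges = elements,
                             colData = DataFrame(sheet,
                                                 row.names = sheet$sample_id))
  new("MethylationExperiment", se)
}

#' Filter elements by per-group sample support
#'
#' Retains elements whose methylation was quantified (non-missing) in at
#' least \code{min_samples} samples of every listed experimental group.
#'
#' @param object a \linkS4class{MethylationExperiment}.
#' @param min_samples minimum quantified samples per group (default 3).
#' @param groups group labels (e.g. \code{c("EOM-pre", "TA-pre")}); defaults
#'   to all groups present in the sample sheet. An empty set leaves the
#'   matrix unchanged.
#' @return the filtered \code{MethylationExperiment}.
#' @export
groupSupportFilter <- function(object, min_samples = 3,
                               groups = unique(sampleGroups(sampleSheet(object)))) {
  if (length(groups) == 0L) return(object)
  sheet <- sampleSheet(object)
  glab <- sampleGroups(sheet)
  unknown <- setdiff(groups, glab)
  if (length(unknown))
    stop("group(s) not in sample sheet: ", paste(unknown, collapse = ", "))
  v <- methValues(object)
  keep <- rep(TRUE, nrow(v))
  for (g in groups) {
    cols <- which(glab == g)
    if (length(cols) < min_samples)
      stop("group ", g, " has only ", length(cols),
           " samples (< min_samples = ", min_samples, ")")
    keep <- keep & rowSums(!is.na(v[, cols, drop = FALSE])) >= min_samples
  }
  object[keep, ]
}

#' Per-sample methylation summary by feature class
#'
#' The \code{genome} class is the unweighted mean of all per-site ratios of
#' the sample; every other class is summarised as the distribution of
#' per-element mean methylation (for violin-style display) plus its mean.
#'
#' @param callsList list of \linkS4class{CpGCallSet}.
#' @param classes named list of element GRanges, e.g.
#'   \code{list(promoter = ..., enhancer = ..., cgi = ...)}.
#' @param min_cpgs minimum covered CpGs per element (default 1: the class
#'   landscape is summarised before any analysis filter).
#' @return list with \code{summary} (data.frame sample_id, class,
#'   mean_meth) and \code{element_means} (class -> element x sample matrix).
#' @export
featureClassSummary <- function(callsList, classes, min_cpgs = 1) {
  ids <- vapply(callsList, sampleId, character(1L))
  rows <- list()
  element_means <- list()
  genome <- vapply(callsList, function(cs) mean(siteRatios(cs)), numeric(1L))
  rows[["genome"]] <- data.frame(sample_id = ids, class = "genome",
                                 mean_meth = genome)
  for (cl in names(classes)) {
    el <- classes[[cl]]
    if (length(el) == 0L) {
      warning("feature class ", cl, " is empty; reported as missing")
      rows[[cl]] <- data.frame(sample_id = ids, class = cl,
                               mean_meth = NA_real_)
      next
    }
    m <- vapply(callsList, function(cs)
      elementMethylation(cs, el, min_cpgs = min_cpgs)$meth,
      numeric(length(el)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(el))
    colnames(m) <- ids
    rownames(m) <- if (is.null(names(el))) NULL else names(el)
    element_means[[cl]] <- m
    rows[[cl]] <- data.frame(sample_id = ids, class = cl,
                             mean_meth = colMeans(m, na.rm = TRUE))
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       element_means = element_means)
}

#' Rolling Z-score differential methylation test
#'
#' For each element the between-group difference of mean methylation is
#' standardised against the mean and standard deviation of differences in a
#' window of elements with the most similar overall methylation: elements
#' are ranked by the two-group mean, and the window of \code{window}
#' nearest-ranked elements (centred, truncated at the ends of the ranking)
#' supplies the local null. p is the two-sided normal tail probability.
#'
#' @param object a \linkS4class{MethylationExperiment}, normally after
#'   \code{\link{groupSupportFilter}} for both groups.
#' @param groupA,groupB group labels; the difference is A - B.
#' @param window window size in elements (default 200, minimum 10).
#' @param alpha significance threshold on p (default 0.05).
#' @return data.frame: element_id, mean_a, mean_b, diff, local_mean,
#'   local_sd, z, p, significant.
#' @export
rollingZTest <- function(object, groupA, groupB, window = 200, alpha = 0.05) {
  if (window < 10) stop("window must be >= 10 elements")
  sheet <- sampleSheet(object)
  glab <- sampleGroups(sheet)
  v <- methValues(object)
  ma <- rowMeansNA(v[, glab == groupA, drop = FALSE])
  mb <- rowMeansNA(v[, glab == groupB, drop = FALSE])
  ok <- !is.na(ma) & !is.na(mb)
  if (sum(ok) < 10)
    stop("fewer than 10 elements quantified in both groups")
  id <- rownames(v)[ok]; ma <- ma[ok]; mb <- mb[ok]
  diff <- ma - mb
  avg <- (ma + mb) / 2
  o <- order(avg)
  ds <- diff[o]
  n <- length(ds)
  h <- floor(window / 2)
  s1 <- c(0, cumsum(ds)); s2 <- c(0, cumsum(ds^2))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  k <- hi - lo + 1
  wsum <- s1[hi + 1L] - s1[lo]
  wsq <- s2[hi + 1L] - s2[lo]
  lmean <- wsum / k
  lvar <- pmax((wsq - k * lmean^2) / (k - 1), 0)
  lsd <- sqrt(lvar)
  z <- ifelse(lsd > 0, (ds - lmean) / lsd, 0)
  res <- data.frame(element_id = id[o], mean_a = ma[o], mean_b = mb[o],
                    diff = ds, local_mean = lmean, local_sd = lsd, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  res$significant <- res$p < alpha
  res[match(id, res$element_id), , drop = FALSE]
}

#' Pool CpG calls across samples
#'
#' Sums methylated and unmethylated counts per (chrom, position) over a
#' list of call sets, yielding the group methylome used for DMR calling.
#'
#' @param callsList list of \linkS4class{CpGCallSet}.
#' @param sampleId identifier for the pooled set.
#' @return a \linkS4class{CpGCallSet}.
#' @export
poolCalls <- function(callsList, sampleId = "pooled") {
  grl <- unname(lapply(callsList, cpgCalls))
  all <- do.call(c, grl)
  key <- paste(as.character(seqnames(all)), start(all))
  nm <- rowsum(mcols(all)$nMeth, key)
  nu <- rowsum(mcols(all)$nUnmeth, key)
  first <- !duplicated(key)
  # align the unique ranges with rowsum's key-sorted rows
  u <- all[first][match(rownames(nm), key[first])]
  CpGCallSet(sampleId, as.character(seqnames(u)), start(u),
             nm[, 1L], nu[, 1L])
}

#' Call differentially methylated regions by the consecutive-CpG rule
#'
#' Per-site group methylation is the pooled ratio
#' 100 * sum(nMeth) / sum(nMeth + nUnmeth); only sites covered in both
#' groups are eligible. A DMR is a maximal run of consecutive eligible
#' sites in which every site differs by at least \code{min_diff}
#' percentage points with one sign, of length at least \code{min_sites}
#' (strictly more than \code{min_sites} when \code{strict = TRUE}).
#'
#' @param callsA,callsB a \linkS4class{CpGCallSet} (already pooled) or a
#'   list of call sets to pool, for each group.
#' @param min_sites minimum run length (default 5).
#' @param min_diff minimum per-site |difference| in percentage points
#'   (default 10).
#' @param strict require run length strictly greater than min_sites.
#' @return GRanges of DMRs spanning first to last constituent site, with
#'   metadata columns n_sites, mean_diff (A - B) and direction
#'   (\code{hyper_in_A} / \code{hypo_in_A}).
#' @export
callDmrs <- function(callsA, callsB, min_sites = 5, min_diff = 10,
                     strict = FALSE) {
  if (is.list(callsA)) callsA <- poolCalls(callsA, "groupA")
  if (is.list(callsB)) callsB <- poolCalls(callsB, "groupB")
  ga <- cpgCalls(callsA); gb <- cpgCalls(callsB)
  keyA <- paste(as.character(seqnames(ga)), start(ga))
  keyB <- paste(as.character(seqnames(gb)), start(gb))
  ia <- which(keyA %in% keyB)
  if (!length(ia)) return(GRanges())
  ib <- match(keyA[ia], keyB)
  chrom <- as.character(seqnames(ga))[ia]
  pos <- start(ga)[ia]
  pa <- siteRatios(callsA)[ia]
  pb <- siteRatios(callsB)[ib]
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  diff <- (pa - pb)[o]
  state <- ifelse(abs(diff) >= min_diff, sign(diff), 0)
  # break runs at chromosome boundaries
  runid <- cumsum(c(TRUE, state[-1L] != state[-length(state)] |
                          chrom[-1L] != chrom[-length(chrom)]))
  out <- list()
  for (r in which(tapply(state, runid, `[`, 1L) != 0)) {
    idx <- which(runid == r)
    len <- length(idx)
    if (if (strict) len > min_sites else len >= min_sites) {
      md <- mean(diff[idx])
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom[idx[1L]], start = pos[idx[1L]], end = pos[idx[len]],
        n_sites = len, mean_diff = md,
        direction = if (md > 0) "hyper_in_A" else "hypo_in_A")
    }
  }
  if (!length(out)) return(GRanges())
  d <- do.call(rbind, out)
  gr <- GRanges(d$chrom, IRanges(d$start, d$end))
  mcols(gr)$n_sites <- d$n_sites
  mcols(gr)$mean_diff <- d$mean_diff
  mcols(gr)$direction <- d$direction
  gr
}

#' Export DMRs as BED6+
#'
#' Score is |mean_diff|, name the direction.
#'
#' @param dmrs GRanges from \code{\link{callDmrs}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDmrBed <- function(dmrs, path) {
  gr <- granges(dmrs, use.mcols = FALSE)
  names(gr) <- mcols(dmrs)$direction
  mcols(gr)$score <- abs(mcols(dmrs)$mean_diff)
  writeBed(gr, path)
}

#' Remove the transplantation effect from post-graft methylomes
#'
#' Per element, the correction coefficient delta is the TA post-graft minus
#' TA pre-graft difference of group mean methylation; delta is subtracted
#' from every post-graft sample (EOM-post and TA-post), making the
#' corrected TA-post group means equal the TA-pre means. Pre-graft samples
#' are untouched. Elements lacking a TA-pre or TA-post value keep their raw
#' values (delta undefined; a message reports how many).
#'
#' @param object a \linkS4class{MethylationExperiment}, normally restricted
#'   to promoter and enhancer elements.
#' @param clamp clamp corrected values into [0, 100] (default TRUE). With
#'   clamping off the TA-post == TA-pre mean identity is exact even for
#'   values that would leave the percentage range.
#' @return the corrected \code{MethylationExperiment}; the per-element
#'   coefficient is stored in \code{rowData(object)$graft_delta}.
#' @export
correctMethylation <- function(object, clamp = TRUE) {
  sheet <- sampleSheet(object)
  glab <- sampleGroups(sheet)
  if (!any(glab == "TA-pre") || !any(glab == "TA-post"))
    stop("TA-pre and TA-post groups are required for the correction")
  v <- methValues(object)
  delta <- rowMeansNA(v[, glab == "TA-post", drop = FALSE]) -
    rowMeansNA(v[, glab == "TA-pre", drop = FALSE])
  undef <- is.na(delta)
  if (any(undef))
    message(sum(undef), " element(s) lack a TA-pre or TA-post value; ",
            "left uncorrected")
  post <- sheet$graft == "post"
  corr <- v
  d <- ifelse(undef, 0, delta)
  corr[, post] <- corr[, post] - d
  if (clamp) corr[, post] <- clamp(corr[, post], 0, 100)
  assays(object)$meth <- corr
  rowData(object)$graft_delta <- delta
  object
}

#' Compare target methylation shifts against a random background subset
#'
#' Tests whether the per-element between-group differences of a target
#' element set depart from those of a seeded random subset of background
#' elements (default n = 350) by Welch's two-sample t test (two-sided).
#'
#' @param object a \linkS4class{MethylationExperiment}.
#' @param target_ids,background_ids element ids; targets are removed from
#'   the background before sampling.
#' @param groupA,groupB group labels; differences are A - B.
#' @param n_background background subset size (default 350).
#' @param seed integer seed for the subset draw; the same seed always draws
#'   the same subset. The global RNG state is left untouched.
#' @return list: mean_shift (mean target diff - mean background diff),
#'   p, t, mean_target, mean_background, n_target, n_background.
#' @export
densityShiftTest <- function(object, target_ids, background_ids,
                             groupA, groupB, n_background = 350, seed = 1) {
  glab <- sampleGroups(sampleSheet(object))
  v <- methValues(object)
  diff <- rowMeansNA(v[, glab == groupA, drop = FALSE]) -
    rowMeansNA(v[, glab == groupB, drop = FALSE])
  names(diff) <- rownames(v)
  target <- diff[intersect(target_ids, names(diff))]
  target <- target[!is.na(target)]
  if (length(target) < 3) stop("target set has fewer than 3 usable elements")
  bg_ids <- setdiff(intersect(background_ids, names(diff)), target_ids)
  bg <- diff[bg_ids]
  bg <- bg[!is.na(bg)]
  if (n_background < length(bg)) {
    rng <- .restoreRNG()
    set.seed(seed)
    bg <- bg[sample.int(length(bg), n_background)]
    rng()
  }
  tt <- stats::t.test(target, bg)
  list(mean_shift = mean(target) - mean(bg),
       p = tt$p.value, t = unname(tt$statistic),
       mean_target = mean(target), mean_background = mean(bg),
       n_target = length(target), n_background = length(bg))
}

# snapshot the global RNG state; returns a restorer function
.restoreRNG <- function() {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  function() {
    if (!is.null(saved)) assign(".Random.seed", saved, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
    invisible(NULL)
  }
}

#' Pooled methylation profile over Hox windows per group
#'
#' Counts are pooled across each group's samples; a window's value is the
#' unweighted mean of per-site pooled ratios over the CpGs it contains,
#' missing when no site is covered.
#'
#' @param callsByGroup named list: group label -> list of
#'   \linkS4class{CpGCallSet}.
#' @param hox_windows GRanges from \code{\link{makeHoxWindows}}.
#' @return matrix windows x groups of mean methylation percent.
#' @export
hoxMethylationProfile <- function(callsByGroup, hox_windows) {
  prof <- vapply(names(callsByGroup), function(g) {
    pooled <- poolCalls(callsByGroup[[g]], g)
    elementMethylation(pooled, hox_windows, min_cpgs = 1)$meth
  }, numeric(length(hox_windows)))
  rownames(prof) <- names(hox_windows)
  prof
}
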