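#' Simulation configuration with study-scale defaults
#'
#' Defaults encode the emulated study conditions: four experimental groups
#' (EOM/TA x pre/post) of 10 samples; 261 EOM-specific and 339 TA-specific
#' planted DEGs (13 of the TA set on Hox clusters); a methylation landscape
#' of roughly 50 percent genome-wide with promoters at 25, enhancers at 30,
#' CpG islands at 5 and repeats at 85; a +2.6-point global post-graft
#' methylation shift; location-specific enhancer hypomethylation at
#' DEG-linked enhancers; and a planted responsive/intermediate/resistant
#' plasticity mixture with 10 percent (EOM-specific) and 20 percent
#' (TA-specific) resistant genes.
#'
#' @param seed integer master seed; every generator draws from a stream
#'   derived from it.
#' @param ... overrides for any default field.
#' @return a list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_samples_per_group = 10L,
    # genes & expression
    n_genes = 3000L,
    n_deg_eom = 261L,
    n_deg_ta = 339L,
    n_hox_ta_degs = 13L,          # TA DEGs located on HoxA/HoxC
    deg_log2fc_range = c(2, 4),   # planted effects are >= 4-fold
    expr_log2rpm_mean = 4,
    expr_log2rpm_sd = 1.5,
    nb_size = 20,                 # negative-binomial dispersion (size)
    library_size = 5e5,
    graft_expr_sd = 0.5,          # per-gene additive log2 graft effect
    plasticity_mix = list(
      EOM = c(responsive = 0.6, intermediate = 0.3, resistant = 0.1),
      TA  = c(responsive = 0.5, intermediate = 0.3, resistant = 0.2)),
    # genome geometry
    gene_spacing = 50000L,
    gene_body_length = 10000L,
    n_extra_peaks = 2600L,
    promoter_peak_frac = 0.2,
    n_cgis = 400L,
    cgi_promoter_frac = 0.3,
    n_repeats = 300L,
    n_background_sites = 30000L,
    # methylation landscape (percent)
    meth_means = c(genome = 50, promoter = 25, enhancer = 30,
                   gene_body = 50, cgi = 5, "repeat" = 85),
    enhancer_meth_sd = 10,        # per-enhancer baseline spread
    enhancer_shift = 25,          # planted group difference at DEG enhancers
    graft_meth_shift = 2.6,       # S-figure-scale global post-graft gain
    cpg_depth = 5,                # Poisson mean read depth per CpG
    # planted DMRs
    n_dmrs = 30L,
    dmr_sites = 8L,
    dmr_spacing = 50L,
    dmr_diff = 30,
    # Hox methylation pattern (percent, HoxA region)
    hox_meth = c(EOM_pre = 20, TA_pre = 80, EOM_post = 60, TA_post = 80),
    hox_other_meth = 30)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(all(cfg$meth_means >= 0 & cfg$meth_means <= 100),
            all(unlist(cfg$plasticity_mix) >= 0 &
                  unlist(cfg$plasticity_mix) <= 1))
  class(cfg) <- "SimulationConfig"
  cfg
}

# evaluate expr under a private RNG stream (config seed + offset),
# restoring the caller's RNG state afterwards (expr is evaluated lazily,
# i.e. after the seed is set)
.withSimSeed <- function(config, offset, expr) {
  restore <- .restoreRNG()
  on.exit(restore())
  set.seed((config$seed * 7L + offset) %% .Machine$integer.max)
  expr
}

#' Simulated sample sheet
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return sample sheet data.frame for the four groups.
#' @export
simulateSampleSheet <- function(config) {
  n <- config$n_samples_per_group
  groups <- expand.grid(muscle = VALID_MUSCLES, graft = VALID_GRAFTS,
                        stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    data.frame(
      sample_id = sprintf("%s_%s_%02d", groups$muscle[i], groups$graft[i],
                          seq_len(n)),
      muscle = groups$muscle[i], graft = groups$graft[i],
      donor_id = sprintf("d%02d", seq_len(n)))
  }))
}

#' Simulate the element annotation
#'
#' Lays out non-overlapping genes on four autosomes plus the four Hox
#' clusters on a fifth chromosome, places one H3K27ac peak near every gene
#' (guaranteeing DEGs an enhancer within 1 Mb), additional intergenic
#' peaks, a configurable fraction of promoter-overlapping peaks (excluded
#' downstream by \code{\link{defineEnhancers}}), CpG islands (a fraction on
#' promoters) and repeat elements. Deterministic under the config seed.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list: genes (gene table), peaks, cgis, repeats (GRanges), and
#'   gene_peak (named map gene_id -> peak name).
#' @export
simulateAnnotation <- function(config) .withSimSeed(config, 1L, {
  sp <- config$gene_spacing
  n <- config$n_genes
  if (sp < 45000L) stop("infeasible config: gene_spacing too small")
  per <- ceiling(n / 4)
  chrom <- rep(paste0("chr", 1:4), each = per)[seq_len(n)]
  idx <- unlist(lapply(paste0("chr", 1:4), function(ch)
    seq_len(sum(chrom == ch))))
  tss <- 25000L + (idx - 1L) * sp
  genes <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(n)),
    chrom = chrom, strand = sample(c("+", "-"), n, replace = TRUE),
    tss = tss, hox_cluster = NA_character_)
  # Hox clusters: 10 genes each on chr5, 8 kb apart, clusters 2 Mb apart
  hox <- do.call(rbind, lapply(seq_along(HOX_CLUSTERS), function(k) {
    data.frame(
      gene_id = sprintf("%s%d", tolower(HOX_CLUSTERS[k]), 1:10),
      chrom = "chr5", strand = "+",
      tss = 2000000L * k + (0:9) * 8000L,
      hox_cluster = HOX_CLUSTERS[k])
  }))
  genes <- rbind(genes, hox)
  # one peak per gene, 1 kb wide, 5-20 kb from the TSS (clear of promoters)
  all_tss <- genes$tss
  off <- sample(c(-1L, 1L), nrow(genes), replace = TRUE) *
    sample(5000:20000, nrow(genes), replace = TRUE)
  gp_start <- pmax(all_tss + off - 500L, 1L)
  gene_peaks <- GRanges(genes$chrom, IRanges(gp_start, width = 1000L))
  names(gene_peaks) <- sprintf("peak_%s", genes$gene_id)
  # intergenic peaks in the 22-28 kb band downstream of random genes
  gx <- sample(seq_len(n), config$n_extra_peaks, replace = TRUE)
  extra <- GRanges(genes$chrom[gx],
                   IRanges(genes$tss[gx] +
                             sample(22000:28000, config$n_extra_peaks,
                                    replace = TRUE), width = 1000L))
  names(extra) <- sprintf("peakx_%04d", seq_len(config$n_extra_peaks))
  n_nonprom <- length(gene_peaks) + length(extra)
  n_prom <- round(config$promoter_peak_frac / (1 - config$promoter_peak_frac) *
                    n_nonprom)
  px <- sample(seq_len(n), n_prom, replace = TRUE)
  # centred on the TSS so the overlap holds on either strand
  promp <- GRanges(genes$chrom[px],
                   IRanges(pmax(genes$tss[px] - 500L, 1L), width = 1000L))
  names(promp) <- sprintf("peakp_%04d", seq_len(n_prom))
  peaks <- c(gene_peaks, extra, promp)
  # CpG islands: a fraction centred on promoters, the rest intergenic
  n_cgi_prom <- round(config$n_cgis * config$cgi_promoter_frac)
  cx <- sample(seq_len(n), config$n_cgis, replace = TRUE)
  cgi_start <- ifelse(seq_len(config$n_cgis) <= n_cgi_prom,
                      genes$tss[cx] - 250L,
                      genes$tss[cx] + sample(32000:34000, config$n_cgis,
                                             replace = TRUE))
  cgis <- GRanges(genes$chrom[cx], IRanges(pmax(cgi_start, 1L), width = 500L))
  names(cgis) <- sprintf("cgi_%04d", seq_len(config$n_cgis))
  # repeats: intergenic 36-40 kb band
  rx <- sample(seq_len(n), config$n_repeats, replace = TRUE)
  repeats <- GRanges(genes$chrom[rx],
                     IRanges(genes$tss[rx] +
                               sample(36000:40000, config$n_repeats,
                                      replace = TRUE), width = 500L))
  names(repeats) <- sprintf("rep_%04d", seq_len(config$n_repeats))
  gene_peak <- stats::setNames(names(gene_peaks), genes$gene_id)
  list(genes = genes, peaks = peaks, cgis = cgis, repeats = repeats,
       gene_peak = gene_peak)
})

# planted DEG identities and plasticity categories (seed stream 2)
.planDegs <- function(config, annotation) .withSimSeed(config, 2L, {
  genes <- annotation$genes
  regular <- genes$gene_id[is.na(genes$hox_cluster)]
  n_hox <- config$n_hox_ta_degs
  hox_ta <- c(sprintf("hoxa%d", 5:10), sprintf("hoxc%d", 4:10))[seq_len(n_hox)]
  picked <- sample(regular, config$n_deg_eom + config$n_deg_ta - n_hox)
  deg_eom <- picked[seq_len(config$n_deg_eom)]
  deg_ta <- c(picked[-seq_len(config$n_deg_eom)], hox_ta)
  deg_truth <- stats::setNames(rep("none", nrow(genes)), genes$gene_id)
  deg_truth[deg_eom] <- "EOM"
  deg_truth[deg_ta] <- "TA"
  mix <- config$plasticity_mix
  pl <- character(0)
  pl[deg_eom] <- sample(names(mix$EOM), length(deg_eom), replace = TRUE,
                        prob = mix$EOM)
  # Hox genes respond to the host niche: responsive or intermediate only
  reg_ta <- setdiff(deg_ta, hox_ta)
  pl[reg_ta] <- sample(names(mix$TA), length(reg_ta), replace = TRUE,
                       prob = mix$TA)
  pl[hox_ta] <- sample(c("responsive", "intermediate"), length(hox_ta),
                       replace = TRUE, prob = c(0.6, 0.4))
  effect <- stats::setNames(
    stats::runif(length(c(deg_eom, deg_ta)), config$deg_log2fc_range[1L],
                 config$deg_log2fc_range[2L]), c(deg_eom, deg_ta))
  list(deg_truth = deg_truth, plasticity_truth = pl, effect = effect)
})

#' Simulate per-sample CpG methylomes with planted ground truth
#'
#' Sites are laid down per element class at its configured landscape mean;
#' enhancers draw per-element baselines (normal, sd
#' \code{enhancer_meth_sd}); enhancers of planted EOM DEGs are
#' hypomethylated in EOM and hypermethylated in TA by half the configured
#' shift each (and mirrored for TA DEGs); DMRs of \code{dmr_sites}
#' consecutive CpGs with \code{dmr_diff}-point differences are planted in
#' reserved intergenic space; the HoxA region is TA-high / EOM-low with a
#' planted post-graft EOM gain; and all post-graft samples gain the global
#' \code{graft_meth_shift}. Per-sample counts are binomial at
#' Poisson-distributed depth (sites drawn at depth 0 are uncovered).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param annotation output of \code{\link{simulateAnnotation}}.
#' @param sheet sample sheet (default \code{simulateSampleSheet(config)}).
#' @return list: \code{calls} (list of \linkS4class{CpGCallSet}) and
#'   \code{truth} (dm_enhancer_truth, dmr_truth, expected class means,
#'   hox_truth, graft_shift).
#' @export
simulateMethylomes <- function(config, annotation,
                               sheet = simulateSampleSheet(config)) {
  plan <- .planDegs(config, annotation)
  .withSimSeed(config, 3L, {
    genes <- annotation$genes
    mm <- config$meth_means
    site_chrom <- character(0); site_pos <- integer(0); site_p <- numeric(0)
    add <- function(chrom, pos, p) {
      site_chrom <<- c(site_chrom, chrom)
      site_pos <<- c(site_pos, as.integer(pos))
      site_p <<- c(site_p, p)
    }
    reg <- is.na(genes$hox_cluster)
    # promoters: 10 sites, 250 bp apart, upstream of the TSS. Hox genes
    # included: their (CGI-like) promoters stay at promoter-level
    # methylation in every group, as for protected Hox promoters.
    for (k in 0:9) add(genes$chrom, genes$tss - 1900L + k * 250L,
                       rep(mm["promoter"], nrow(genes)))
    # gene bodies: 10 sites, 1 kb apart
    for (k in 1:10) add(genes$chrom, genes$tss + k * 1000L,
                        rep(mm["gene_body"], nrow(genes)))
    # CpG islands: 10 sites, 50 bp apart
    cg <- annotation$cgis
    for (k in 0:9) add(as.character(seqnames(cg)), start(cg) + k * 50L,
                       rep(mm["cgi"], length(cg)))
    # repeats: 5 sites, 100 bp apart
    rp <- annotation$repeats
    for (k in 0:4) add(as.character(seqnames(rp)), start(rp) + k * 100L,
                       rep(mm["repeat"], length(rp)))
    # background sites: intergenic 41-48 kb band of random regular genes
    bx <- sample(which(reg), config$n_background_sites, replace = TRUE)
    add(genes$chrom[bx],
        genes$tss[bx] + sample(41000:48000, config$n_background_sites,
                               replace = TRUE), rep(mm["genome"],
                                                    config$n_background_sites))
    # enhancer peaks (gene-linked and intergenic; promoter-overlapping
    # peaks are not enhancers and carry no sites)
    pk <- annotation$peaks[!grepl("^peakp_", names(annotation$peaks))]
    n_sites_pk <- 2L + stats::rpois(length(pk), 6)
    base <- clamp(stats::rnorm(length(pk), mm["enhancer"],
                               config$enhancer_meth_sd), 5, 95)
    pk_chrom <- rep(as.character(seqnames(pk)), n_sites_pk)
    pk_off <- unlist(lapply(n_sites_pk, function(k) seq_len(k) - 1L)) * 100L
    pk_pos <- rep(start(pk), n_sites_pk) + 50L + pk_off
    pk_p <- rep(base, n_sites_pk)
    enh_site_of <- rep(names(pk), n_sites_pk)
    # planted differential enhancers: the peak linked to each planted DEG
    dm_shift <- stats::setNames(numeric(length(pk)), names(pk))
    degs <- names(plan$deg_truth)[plan$deg_truth != "none"]
    dm_peaks <- unname(annotation$gene_peak[degs])
    spec <- plan$deg_truth[degs]
    s <- config$enhancer_shift
    # diff is EOM - TA: negative for EOM-linked (hypo in EOM), positive for TA
    dm_shift[dm_peaks] <- ifelse(spec == "EOM", -s, s)
    n_sites <- length(site_p)
    # group probability matrix for the non-enhancer sites
    groups <- c("EOM_pre", "TA_pre", "EOM_post", "TA_post")
    P <- matrix(rep(site_p, 4L), ncol = 4L,
                dimnames = list(NULL, groups))
    half <- dm_shift[enh_site_of] / 2
    Pe <- cbind(EOM_pre = pk_p + half, TA_pre = pk_p - half,
                EOM_post = pk_p + half, TA_post = pk_p - half)
    chrom <- c(site_chrom, pk_chrom)
    pos <- c(site_pos, pk_pos)
    P <- rbind(P, Pe)
    # planted DMRs: dmr_sites consecutive CpGs at 30-31 kb of chosen genes
    nd <- config$n_dmrs
    dg <- sample(which(reg), nd)
    dmr_chrom <- rep(genes$chrom[dg], each = config$dmr_sites)
    dmr_pos <- rep(genes$tss[dg] + 30000L, each = config$dmr_sites) +
      (seq_len(config$dmr_sites) - 1L) * config$dmr_spacing
    dmr_dir <- rep(rep(c(1, -1), length.out = nd), each = config$dmr_sites)
    dmr_p <- 50 + dmr_dir * config$dmr_diff / 2
    Pd <- cbind(EOM_pre = dmr_p, TA_pre = 100 - dmr_p,
                EOM_post = dmr_p, TA_post = 100 - dmr_p)
    chrom <- c(chrom, dmr_chrom)
    pos <- c(pos, dmr_pos)
    P <- rbind(P, Pd)
    # Hox cluster sites: 200 bp apart across each cluster span +- 5 kb
    for (cl in HOX_CLUSTERS) {
      g <- genes[!is.na(genes$hox_cluster) & genes$hox_cluster == cl, ]
      hpos <- seq(min(g$tss) - 5000L, max(g$tss) + 5000L, by = 200L)
      # the location-differential pattern spares the protected promoters
      inprom <- rep(FALSE, length(hpos))
      for (t in g$tss) inprom <- inprom | (hpos >= t - 2000L & hpos <= t + 500L)
      hpos <- hpos[!inprom]
      if (cl == "HoxA") {
        hm <- config$hox_meth
        Ph <- cbind(EOM_pre = rep(hm["EOM_pre"], length(hpos)),
                    TA_pre = hm["TA_pre"], EOM_post = hm["EOM_post"],
                    TA_post = hm["TA_post"])
      } else {
        Ph <- matrix(config$hox_other_meth, length(hpos), 4L,
                     dimnames = list(NULL, groups))
      }
      chrom <- c(chrom, rep(g$chrom[1L], length(hpos)))
      pos <- c(pos, as.integer(hpos))
      P <- rbind(P, Ph)
    }
    # global post-graft shift, then keep probabilities in range
    P[, c("EOM_post", "TA_post")] <- P[, c("EOM_post", "TA_post")] +
      config$graft_meth_shift
    P <- clamp(P, 0.5, 99.5) / 100
    # element classes can collide on a position (e.g. a CGI on a promoter);
    # the first-laid site wins so each (chrom, pos) is a single CpG
    key <- paste(chrom, pos)
    first <- !duplicated(key)
    chrom <- chrom[first]; pos <- pos[first]; P <- P[first, , drop = FALSE]
    # expected class means for recovery checks: per-element mean of true
    # site levels, averaged over elements (the featureClassSummary view)
    classElems <- list(promoter = makePromoters(genes),
                       enhancer = pk, cgi = cg, "repeat" = rp)
    siteGr <- GRanges(chrom, IRanges(pos, width = 1L))
    expected <- lapply(classElems, function(el) {
      ov <- findOverlaps(siteGr, el, ignore.strand = TRUE)
      sums <- rowsum(cbind(P[queryHits(ov), , drop = FALSE], 1),
                     subjectHits(ov))
      colMeans(100 * sums[, 1:4, drop = FALSE] / sums[, 5L])
    })
    expected$genome <- colMeans(100 * P)
    # per-sample draws
    glab <- paste(sheet$muscle, sheet$graft, sep = "_")
    calls <- lapply(seq_len(nrow(sheet)), function(i) {
      depth <- stats::rpois(length(pos), config$cpg_depth)
      cov <- depth > 0L
      nm <- stats::rbinom(sum(cov), depth[cov], P[cov, glab[i]])
      CpGCallSet(sheet$sample_id[i], chrom[cov], pos[cov], nm,
                 depth[cov] - nm)
    })
    names(calls) <- sheet$sample_id
    dmr_truth <- data.frame(
      chrom = genes$chrom[dg], start = genes$tss[dg] + 30000L,
      end = genes$tss[dg] + 30000L +
        (config$dmr_sites - 1L) * config$dmr_spacing,
      n_sites = config$dmr_sites,
      diff = rep(c(1, -1), length.out = nd) * config$dmr_diff)
    truth <- list(
      dm_enhancer_truth = dm_shift[dm_shift != 0],
      dmr_truth = dmr_truth,
      expected_class_meth = expected,
      hox_truth = list(HoxA = as.list(config$hox_meth),
                       other = config$hox_other_meth),
      graft_shift = config$graft_meth_shift)
    list(calls = calls, truth = truth)
  })
}

#' Simulate the count matrix with planted DEGs, graft effect and plasticity
#'
#' Counts are negative binomial around group-specific means: baseline
#' log2 RPM drawn log-normally per gene; planted DEGs shifted in their
#' specific muscle by a >= 4-fold effect; a per-gene additive log2 graft
#' effect applied identically to all post-graft samples (exactly removable
#' by \code{\link{correctExpression}}); and the post-graft EOM mean of
#' every planted DEG set by its plasticity category (responsive: TA-pre
#' level, resistant: EOM-pre level, intermediate: midpoint) before noise.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param annotation output of \code{\link{simulateAnnotation}}.
#' @param sheet sample sheet (default \code{simulateSampleSheet(config)}).
#' @return list: \code{counts} (genes x samples integer matrix),
#'   \code{sheet}, and \code{truth} (deg_truth, plasticity_truth, effect,
#'   graft_effect).
#' @export
simulateCounts <- function(config, annotation,
                           sheet = simulateSampleSheet(config)) {
  plan <- .planDegs(config, annotation)
  .withSimSeed(config, 4L, {
    genes <- annotation$genes
    ng <- nrow(genes)
    base <- clamp(stats::rnorm(ng, config$expr_log2rpm_mean,
                               config$expr_log2rpm_sd), 0.5, 12)
    names(base) <- genes$gene_id
    muE <- muT <- base   # pre-graft group means, log2 RPM
    degs <- names(plan$deg_truth)[plan$deg_truth != "none"]
    spec <- plan$deg_truth[degs]
    eff <- plan$effect[degs]
    muE[degs[spec == "EOM"]] <- base[degs[spec == "EOM"]] + eff[spec == "EOM"]
    muT[degs[spec == "TA"]] <- base[degs[spec == "TA"]] + eff[spec == "TA"]
    # post-graft EOM means follow the planted plasticity category
    muEpost <- muE
    pl <- plan$plasticity_truth
    resp <- degs[pl[degs] == "responsive"]
    inter <- degs[pl[degs] == "intermediate"]
    muEpost[resp] <- muT[resp]
    muEpost[inter] <- (muE[inter] + muT[inter]) / 2
    gamma <- stats::rnorm(ng, 0, config$graft_expr_sd)
    mu <- cbind(EOM_pre = muE, TA_pre = muT,
                EOM_post = muEpost + gamma, TA_post = muT + gamma)
    # convert log2 RPM targets to NB count means, fixing library size
    lam <- apply(mu, 2L, function(m) {
      rpm <- pmax(2^m - 1, 0)   # the graft effect can push a mean below 0
      rpm * config$library_size / 1e6 * (1e6 / sum(rpm))
    })
    glab <- paste(sheet$muscle, sheet$graft, sep = "_")
    counts <- vapply(seq_len(nrow(sheet)), function(i)
      stats::rnbinom(ng, mu = lam[, glab[i]], size = config$nb_size),
      numeric(ng))
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(genes$gene_id, sheet$sample_id)
    truth <- list(deg_truth = plan$deg_truth,
                  plasticity_truth = plan$plasticity_truth,
                  effect = plan$effect, graft_effect = gamma)
    list(counts = counts, sheet = sheet, truth = truth)
  })
}

#' Simulate the complete study dataset
#'
#' Runs annotation, methylome and count simulation under one seed and
#' merges the planted ground truth.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list: annotation, sheet, calls, counts, truth.
#' @export
simulateStudy <- function(config = simulationConfig()) {
  annotation <- simulateAnnotation(config)
  sheet <- simulateSampleSheet(config)
  meth <- simulateMethylomes(config, annotation, sheet)
  expr <- simulateCounts(config, annotation, sheet)
  list(annotation = annotation, sheet = sheet, calls = meth$calls,
       counts = expr$counts, truth = c(expr$truth, meth$truth))
}

#' Write the planted ground truth as JSON
#'
#' @param truth the \code{truth} element of \code{\link{simulateStudy}}.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  # named atomic vectors serialize as JSON objects so names survive
  objectify <- function(x) {
    if (is.data.frame(x)) x
    else if (is.list(x)) lapply(x, objectify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(objectify(truth), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a ground-truth JSON written by \code{\link{writeGroundTruth}}
#'
#' @param path JSON file.
#' @return the truth list with named numeric vectors restored.
#' @export
readGroundTruth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("deg_truth", "plasticity_truth", "effect", "graft_effect",
              "dm_enhancer_truth"))
    if (!is.null(tr[[f]])) tr[[f]] <- unlist(tr[[f]])
  if (!is.null(tr$dmr_truth)) tr$dmr_truth <- as.data.frame(tr$dmr_truth)
  tr
}

#' Write a simulated dataset to disk in the package's exchange formats
#'
#' BED for peaks/CGIs/repeats, Bismark-style coverage per sample, TSV for
#' counts, gene table and sample sheet, JSON for the ground truth.
#'
#' @param study output of \code{\link{simulateStudy}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBed(study$annotation$peaks, file.path(dir, "peaks.bed"))
  writeBed(study$annotation$cgis, file.path(dir, "cgis.bed"))
  writeBed(study$annotation$repeats, file.path(dir, "repeats.bed"))
  fwrite(study$annotation$genes, file.path(dir, "genes.tsv"), sep = "\t",
         na = "NA", quote = FALSE)
  fwrite(study$sheet, file.path(dir, "samples.tsv"), sep = "\t",
         quote = FALSE)
  cnt <- data.frame(gene_id = rownames(study$counts), study$counts,
                    check.names = FALSE)
  fwrite(cnt, file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE)
  for (s in names(study$calls))
    writeCoverage(study$calls[[s]], file.path(dir, paste0(s, ".cov.gz")))
  writeGroundTruth(study$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
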