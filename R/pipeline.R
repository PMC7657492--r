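#' Pipeline run configuration
#'
#' Collects every analysis threshold with its published default: promoter
#' bounds -2000/+500, 1 Mb enhancer-gene link distance, >= 2 covered CpGs
#' per element, >= 3 quantified samples per group, fold change > 2 and
#' p < 0.05 for DEGs, DMR rule of 5 consecutive sites at 10-point
#' differences, rolling-Z window of 200 elements, 25/75 classification
#' bounds, and the 350-element random background subset.
#'
#' @param seed integer seed used by the seeded stages.
#' @param ... overrides for any default field.
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(seed = 1, ...) {
  cfg <- list(seed = as.integer(seed),
              promoter_upstream = 2000, promoter_downstream = 500,
              link_max_distance = 1e6,
              min_cpgs = 2, min_samples = 3,
              fc_threshold = 2, alpha = 0.05,
              dmr_min_sites = 5, dmr_min_diff = 10,
              rolling_window = 200,
              class_lower = 25, class_upper = 75,
              n_background = 350,
              gene_body_length = 10000,
              hox_window = 1000, hox_flank = 5000)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "RunConfig"
  cfg
}

#' Write / read a run configuration as YAML
#'
#' @param config a \code{\link{runConfig}}.
#' @param path YAML file.
#' @return \code{path} invisibly, or the restored \code{RunConfig}.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  do.call(runConfig, yaml::read_yaml(path))
}

#' Fixed-extent gene bodies from a gene table
#'
#' When the gene table carries no gene ends, gene bodies are taken as a
#' fixed extent downstream of the TSS in transcription orientation.
#'
#' @param genes gene table.
#' @param length extent in bp (default 10 kb).
#' @return GRanges named by gene_id with \code{elementClass = "gene_body"}.
#' @export
makeGeneBodies <- function(genes, length = 10000) {
  plus <- genes$strand == "+"
  start1 <- ifelse(plus, genes$tss, pmax(genes$tss - length + 1L, 1L))
  end1 <- ifelse(plus, genes$tss + length - 1L, genes$tss)
  gr <- GRanges(genes$chrom, IRanges(start1, end1), strand = genes$strand)
  names(gr) <- genes$gene_id
  mcols(gr)$elementClass <- "gene_body"
  gr
}

# combine promoter + enhancer element universe with distinct names
.regulatoryElements <- function(promoters, enhancers) {
  names(promoters) <- paste0("prom_", names(promoters))
  mcols(promoters) <- mcols(promoters)[, c("elementClass", "gene_id")]
  mc <- DataFrame(elementClass = mcols(enhancers)$elementClass,
                  gene_id = if ("gene_id" %in% colnames(mcols(enhancers)))
                    mcols(enhancers)$gene_id else NA_character_)
  mcols(enhancers) <- mc
  c(promoters, enhancers)
}

#' Location contrast: pre-graft EOM vs TA transcriptome and methylome
#'
#' Runs the pre-graft arm of the pipeline: element annotation
#' (promoters, CGI split, enhancers, enhancer-gene links), differential
#' expression, element methylation with the coverage and group-support
#' filters, the feature-class landscape, rolling Z-score differential
#' enhancer methylation, DMR calling, and the expression / promoter /
#' enhancer PCAs.
#'
#' @param study list with annotation (genes, peaks, cgis, repeats), sheet,
#'   calls and counts — as returned by \code{\link{simulateStudy}} or
#'   assembled from the readers.
#' @param config a \code{\link{runConfig}}.
#' @return list of stage outputs (see details in the vignette).
#' @export
runLocationContrast <- function(study, config = runConfig()) {
  genes <- study$annotation$genes
  sheet <- study$sheet
  validateSampleSheet(sheet)
  promoters <- makePromoters(genes, config$promoter_upstream,
                             config$promoter_downstream)
  cgi_split <- splitPromotersByCgi(promoters, study$annotation$cgis)
  enhancers <- defineEnhancers(study$annotation$peaks, promoters)
  enhancers <- linkEnhancersToGenes(enhancers, genes,
                                    config$link_max_distance)
  message("annotation: ", length(promoters), " promoters (",
          length(cgi_split$cgi_promoters), " CGI), ", length(enhancers),
          " enhancers (", sum(!is.na(mcols(enhancers)$gene_id)), " linked)")
  expr <- expressionExperiment(study$counts, sheet, genes)
  degs <- differentialExpression(expr, "EOM-pre", "TA-pre",
                                 config$fc_threshold, config$alpha)
  message("expression: ", sum(degs$specificity == "EOM"), " EOM / ",
          sum(degs$specificity == "TA"), " TA DEGs")
  elements <- .regulatoryElements(promoters, enhancers)
  meth <- methylationExperiment(study$calls, elements, sheet,
                                config$min_cpgs)
  pre <- c("EOM-pre", "TA-pre")
  methf <- groupSupportFilter(meth, config$min_samples, pre)
  message("methylation: ", nrow(methf), "/", nrow(meth),
          " elements pass the coverage and group-support filters")
  classes <- list(promoter = promoters, enhancer = enhancers,
                  gene_body = makeGeneBodies(genes, config$gene_body_length),
                  cgi = study$annotation$cgis,
                  "repeat" = study$annotation$repeats)
  class_summary <- featureClassSummary(study$calls, classes)
  is_enh <- rowRanges(methf)$elementClass == "enhancer"
  rollz <- rollingZTest(methf[is_enh, ], "EOM-pre", "TA-pre",
                        config$rolling_window, config$alpha)
  message("rolling Z: ", sum(rollz$significant), "/", nrow(rollz),
          " enhancers differentially methylated")
  glab <- sampleGroups(sheet)
  dmrs <- callDmrs(study$calls[glab == "EOM-pre"],
                   study$calls[glab == "TA-pre"],
                   config$dmr_min_sites, config$dmr_min_diff)
  message("DMRs: ", length(dmrs))
  pre_samp <- sheet$sample_id[glab %in% pre]
  mv <- methValues(methf)
  deg_ids <- degs$gene_id[degs$specificity != "none"]
  deg_enh <- names(enhancers)[mcols(enhancers)$gene_id %in% deg_ids]
  pcas <- list(
    expression = runPCA(log2rpm(expr)[, pre_samp]),
    promoter = runPCA(mv[rowRanges(methf)$elementClass == "promoter",
                         pre_samp]),
    enhancer = runPCA(mv[is_enh, pre_samp]),
    deg_enhancer = runPCA(mv[, pre_samp], feature_subset = deg_enh))
  list(config = config, promoters = promoters, cgi_split = cgi_split,
       enhancers = enhancers, expr = expr, degs = degs, meth = meth,
       meth_filtered = methf, class_summary = class_summary,
       rolling_z = rollz, dmrs = dmrs, pcas = pcas, deg_enhancers = deg_enh)
}

#' Graft analysis: corrected post-graft transcriptome and methylome
#'
#' Runs the transplantation arm on top of \code{\link{runLocationContrast}}
#' output: graft-effect correction of expression and methylation,
#' plasticity rescaling and classification of location-specific genes with
#' their category fractions and the direction-of-shift table,
#' DEG-restricted expression PCA, corrected methylation PCAs, post-graft
#' enhancer density-shift tests, correlation clustering, and Hox expression
#' and methylation profiles.
#'
#' @param study as in \code{\link{runLocationContrast}}.
#' @param location output of \code{\link{runLocationContrast}} (recomputed
#'   when NULL).
#' @param config a \code{\link{runConfig}}.
#' @return list of stage outputs.
#' @export
runGraftAnalysis <- function(study, location = NULL, config = runConfig()) {
  if (is.null(location)) location <- runLocationContrast(study, config)
  sheet <- study$sheet
  glab <- sampleGroups(sheet)
  if (!any(glab == "TA-post"))
    stop("graft analysis requires the TA-post group (correction impossible)")
  cexpr <- correctExpression(location$expr)
  calls <- rescaleAndClassify(cexpr, location$degs, "EOM-post",
                              config$class_lower, config$class_upper)
  fractions <- plasticityFractions(calls)
  # direction of post-graft movement of location-specific genes (EOM cells)
  x <- log2rpm(cexpr)
  idx <- match(calls$gene_id, rownames(x))
  moved <- rowMeans(x[idx, glab == "EOM-post", drop = FALSE]) -
    rowMeans(x[idx, glab == "EOM-pre", drop = FALSE])
  shift_table <- data.frame(
    specificity = c("TA", "EOM"),
    fraction_moved_toward_host = c(
      mean(moved[calls$specificity == "TA"] > 0),
      mean(moved[calls$specificity == "EOM"] < 0)))
  cmeth <- correctMethylation(location$meth_filtered)
  mv <- methValues(cmeth)
  rr <- rowRanges(cmeth)
  tri <- sheet$sample_id[glab %in% c("EOM-pre", "TA-pre", "EOM-post")]
  deg_ids <- location$degs$gene_id[location$degs$specificity != "none"]
  deg_prom <- rownames(mv)[rr$elementClass == "promoter" &
                             rr$gene_id %in% deg_ids]
  pcas <- list(
    deg_expression = runPCA(x[, tri], feature_subset = deg_ids),
    whole_expression = runPCA(x),
    promoter = runPCA(mv[, tri], feature_subset = deg_prom),
    enhancer = runPCA(mv[, tri], feature_subset = location$deg_enhancers))
  enh <- location$enhancers
  eom_enh <- names(enh)[mcols(enh)$gene_id %in%
                          location$degs$gene_id[location$degs$specificity == "EOM"]]
  ta_enh <- names(enh)[mcols(enh)$gene_id %in%
                         location$degs$gene_id[location$degs$specificity == "TA"]]
  all_enh <- rownames(mv)[rr$elementClass == "enhancer"]
  density_shift <- list(
    EOM = densityShiftTest(cmeth, eom_enh, all_enh, "EOM-post", "EOM-pre",
                           config$n_background, config$seed),
    TA = densityShiftTest(cmeth, ta_enh, all_enh, "EOM-post", "EOM-pre",
                          config$n_background, config$seed + 1L))
  clustering <- correlationClustering(x[deg_ids, tri])
  genes <- study$annotation$genes
  hox_expr <- hoxExpressionProfile(cexpr)
  hoxa <- makeHoxWindows(genes, "HoxA", config$hox_window, config$hox_flank)
  callsByGroup <- lapply(c("EOM-pre", "TA-pre", "EOM-post"), function(g)
    study$calls[glab == g])
  names(callsByGroup) <- c("EOM-pre", "TA-pre", "EOM-post")
  hox_meth <- hoxMethylationProfile(callsByGroup, hoxa)
  list(config = config, expr_corrected = cexpr, meth_corrected = cmeth,
       plasticity = calls, fractions = fractions, shift_table = shift_table,
       pcas = pcas, density_shift = density_shift, clustering = clustering,
       hox_expression = hox_expr, hox_methylation = hox_meth)
}

#' Write a run report to a directory
#'
#' Serialises the configuration (with an md5 provenance hash named in every
#' output) plus the main tables: DEGs, rolling-Z results, DMRs (BED),
#' methylation matrices, PCA scores, plasticity calls and fractions, Hox
#' profiles and the sample dendrogram (Newick).
#'
#' @param location output of \code{\link{runLocationContrast}}.
#' @param graft optional output of \code{\link{runGraftAnalysis}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeRunReport <- function(location, graft = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfgfile <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(location$config), cfgfile, auto_unbox = TRUE)
  hash <- unname(tools::md5sum(cfgfile))
  seed <- location$config$seed
  stamp <- function(path) {
    writeLines(sprintf("# config %s seed %d", hash, seed), path)
    path
  }
  wtab <- function(d, name) {
    p <- stamp(file.path(dir, name))
    suppressWarnings(fwrite(d, p, sep = "\t", quote = FALSE, na = "NA",
                            append = TRUE, col.names = TRUE))
  }
  wtab(location$degs, "degs.tsv")
  wtab(location$rolling_z, "rolling_z.tsv")
  wtab(location$class_summary$summary, "class_summary.tsv")
  if (length(location$dmrs))
    writeDmrBed(location$dmrs, file.path(dir, "dmrs.bed"))
  writeMatrixTsv(methValues(location$meth_filtered),
                 file.path(dir, "methylation.tsv"), "element_id")
  exportElements(location$enhancers, file.path(dir, "enhancers.bed"))
  for (nm in names(location$pcas))
    wtab(data.frame(sample_id = rownames(location$pcas[[nm]]$scores),
                    location$pcas[[nm]]$scores[, 1:2, drop = FALSE]),
         sprintf("pca_%s.tsv", nm))
  if (!is.null(graft)) {
    wtab(graft$plasticity, "plasticity.tsv")
    wtab(graft$fractions, "plasticity_fractions.tsv")
    wtab(graft$shift_table, "shift_table.tsv")
    wtab(graft$hox_expression, "hox_expression.tsv")
    wtab(data.frame(window = rownames(graft$hox_methylation),
                    graft$hox_methylation, check.names = FALSE),
         "hox_methylation.tsv")
    writeNewick(graft$clustering$hclust, file.path(dir, "clustering.nwk"))
  }
  invisible(dir)
}
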