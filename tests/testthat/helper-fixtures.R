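# shared fixtures and independent oracles for the test suite

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
  library(withr)
})

.fixture_env <- new.env(parent = emptyenv())

# the default synthetic study (the study-scale conditions), built once
defaultStudy <- function() {
  if (is.null(.fixture_env$study))
    .fixture_env$study <- simulateStudy(simulationConfig(seed = 42))
  .fixture_env$study
}

defaultLocation <- function() {
  if (is.null(.fixture_env$location))
    .fixture_env$location <- suppressMessages(
      runLocationContrast(defaultStudy(), runConfig(seed = 42)))
  .fixture_env$location
}

defaultGraft <- function() {
  if (is.null(.fixture_env$graft))
    .fixture_env$graft <- suppressMessages(
      runGraftAnalysis(defaultStudy(), defaultLocation(),
                       runConfig(seed = 42)))
  .fixture_env$graft
}

# minimal four-group sample sheet
toySheet <- function(n = 3) {
  do.call(rbind, lapply(c("EOM", "TA"), function(m)
    do.call(rbind, lapply(c("pre", "post"), function(g)
      data.frame(sample_id = sprintf("%s_%s_%02d", m, g, seq_len(n)),
                 muscle = m, graft = g,
                 donor_id = sprintf("d%02d", seq_len(n)))))))
}

# CpGCallSet from a compact spec: data.frame(chrom, pos, nMeth, nUnmeth)
toyCalls <- function(df, id = "s1") {
  CpGCallSet(id, df$chrom, df$pos, df$nMeth, df$nUnmeth)
}

# ---- independent oracles ---------------------------------------------------

# brute-force DMR enumeration: for every start index scan forward while
# every site qualifies with one sign; report maximal runs >= min_sites.
# Deliberately O(n^2) and structured differently from the caller.
bruteForceDmrs <- function(chrom, pos, pctA, pctB, min_sites = 5,
                           min_diff = 10) {
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  diff <- (pctA - pctB)[o]
  n <- length(diff)
  qual <- function(i, s) chrom[i] == chrom[s] && abs(diff[i]) >= min_diff &&
    sign(diff[i]) == sign(diff[s])
  out <- list()
  i <- 1L
  for (i in seq_len(n)) {
    if (abs(diff[i]) < min_diff) next
    # maximality: previous site must not extend the run
    if (i > 1L && qual(i - 1L, i)) next
    j <- i
    while (j < n && qual(j + 1L, i)) j <- j + 1L
    if (j - i + 1L >= min_sites)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom[i], start = pos[i], end = pos[j],
        n_sites = j - i + 1L, mean_diff = mean(diff[i:j]))
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# brute-force nearest-TSS search with the lexicographic tie rule
bruteForceNearest <- function(mid, chrom, genes, max_distance = 1e6) {
  vapply(seq_along(mid), function(i) {
    g <- genes[genes$chrom == chrom[i], ]
    if (!nrow(g)) return(NA_character_)
    d <- abs(g$tss - mid[i])
    dmin <- min(d)
    if (dmin > max_distance) return(NA_character_)
    min(g$gene_id[d == dmin])
  }, character(1L))
}
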