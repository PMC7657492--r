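test_that("log2 RPM normalisation follows the closed form", {
  counts <- matrix(c(0, 1, 999999, 0, 2, 999998), ncol = 2,
                   dimnames = list(c("g0", "g1", "gL"), c("s1", "s2")))
  x <- normalizeLog2Rpm(counts)                # library size exactly 1e6
  expect_equal(x["g0", "s1"], 0)           # zero count maps to zero
  expect_equal(x["g1", "s1"], 1)           # 1 read in 1e6 -> log2(2)
  expect_equal(x["gL", "s1"], log2(999999 + 1))
  # c = L (single expressed gene): log2(1e6 + 1)
  solo <- matrix(c(5000), dimnames = list("g", "s"))
  expect_equal(normalizeLog2Rpm(solo)[1], log2(1e6 + 1))
  # monotone in counts within a sample, invariant to gene order
  expect_true(all(diff(x[order(counts[, 1]), 1]) >= 0))
  expect_error(normalizeLog2Rpm(matrix(0, 2, 1)), "library size")
})

test_that("differential expression applies both thresholds with direction", {
  withr::local_seed(41)
  sheet <- toySheet(5)
  n <- 200
  x <- matrix(rnbinom(n * nrow(sheet), mu = 200, size = 20), n,
              dimnames = list(sprintf("g%03d", 1:n), sheet$sample_id))
  eom_pre <- sampleGroups(sheet) == "EOM-pre"
  x[1:10, eom_pre] <- rnbinom(10 * sum(eom_pre), mu = 3200, size = 20)
  ee <- expressionExperiment(x, sheet)
  degs <- differentialExpression(ee)
  expect_true(all(degs$specificity[1:10] == "EOM"))
  expect_true(all(degs$log2fc[1:10] > 1))
  # DEG iff both |log2fc| > 1 and p < alpha
  hit <- degs$specificity != "none"
  expect_identical(hit, abs(degs$log2fc) > 1 & degs$p < 0.05)
  # antisymmetric under group exchange
  rev <- differentialExpression(ee, "TA-pre", "EOM-pre")
  expect_equal(rev$log2fc, -degs$log2fc)
  expect_equal(rev$p, degs$p)
  expect_true(all(rev$specificity[1:10] == "EOM"))
})

test_that("the Welch statistic matches stats::t.test gene by gene", {
  withr::local_seed(43)
  sheet <- toySheet(4)
  x <- matrix(rnorm(30 * nrow(sheet), 6, 1), 30,
              dimnames = list(sprintf("g%02d", 1:30), sheet$sample_id))
  counts <- matrix(rpois(length(x), 100), nrow(x),
                   dimnames = dimnames(x))
  ee <- expressionExperiment(counts, sheet)
  assays(ee)$log2rpm <- x
  degs <- differentialExpression(ee)
  glab <- sampleGroups(sheet)
  for (g in c(1, 7, 30)) {
    tt <- t.test(x[g, glab == "EOM-pre"], x[g, glab == "TA-pre"])
    expect_equal(degs$p[g], tt$p.value, tolerance = 1e-12)
    expect_equal(degs$log2fc[g], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-12)
  }
  # degenerate dispersion: both groups constant and equal -> p = 1
  flat <- counts
  flat[1, ] <- 50
  ee2 <- expressionExperiment(flat, sheet)
  l <- log2rpm(ee2)
  l[1, ] <- 5
  assays(ee2)$log2rpm <- l
  expect_equal(differentialExpression(ee2)$p[1], 1)
})

test_that("expression correction removes the graft effect exactly", {
  withr::local_seed(47)
  sheet <- toySheet(4)
  counts <- matrix(rpois(40 * nrow(sheet), 150), 40,
                   dimnames = list(sprintf("g%02d", 1:40), sheet$sample_id))
  ee <- expressionExperiment(counts, sheet)
  x <- log2rpm(ee)
  post <- sheet$graft == "post"
  x[, post] <- x[, post] + 2          # planted uniform graft effect
  assays(ee)$log2rpm <- x
  corr <- correctExpression(ee)
  xc <- log2rpm(corr)
  glab <- sampleGroups(sheet)
  expect_equal(rowMeans(xc[, glab == "TA-post"]),
               rowMeans(xc[, glab == "TA-pre"]), tolerance = 1e-12)
  # the EOM-post shift of exactly delta = 2 is undone
  expect_equal(xc[, glab == "EOM-post"],
               log2rpm(ee)[, glab == "EOM-post"] -
                 rowData(corr)$graft_delta, tolerance = 1e-12)
  # delta = 0 is the identity
  ee0 <- expressionExperiment(counts, sheet)
  x0 <- log2rpm(ee0)
  glab0 <- sampleGroups(sheet)
  x0[, glab0 == "TA-post"] <- x0[, glab0 == "TA-pre"]
  assays(ee0)$log2rpm <- x0
  expect_equal(log2rpm(correctExpression(ee0)), x0, tolerance = 1e-12)
})

test_that("rescaling maps pre-graft means to 0/100 and classifies", {
  sheet <- toySheet(3)
  glab <- sampleGroups(sheet)
  mk <- function(eom_pre, ta_pre, eom_post) {
    x <- matrix(0, 5, nrow(sheet),
                dimnames = list(sprintf("g%d", 1:5), sheet$sample_id))
    x[, glab == "EOM-pre"] <- eom_pre
    x[, glab == "TA-pre"] <- ta_pre
    x[, glab == "EOM-post"] <- eom_post
    x[, glab == "TA-post"] <- ta_pre
    counts <- matrix(10L, 5, nrow(sheet), dimnames = dimnames(x))
    ee <- expressionExperiment(counts, sheet)
    assays(ee)$log2rpm <- x
    ee
  }
  degs <- data.frame(gene_id = sprintf("g%d", 1:5),
                     specificity = c("TA", "EOM", "TA", "TA", "TA"))
  # g-wise values: m_EOM, m_TA, x_post per construction below
  ee <- mk(eom_pre = c(2, 5, 2, 2, 2), ta_pre = c(6, 1, 6, 6, 6),
           eom_post = c(6, 1, 4, 1, 3))
  calls <- rescaleAndClassify(ee, degs)
  sc <- setNames(calls$rescaled_score, calls$gene_id)
  ct <- setNames(calls$category, calls$gene_id)
  expect_equal(sc[["g1"]], 100)            # TA gene at TA level
  expect_equal(ct[["g1"]], "responsive")
  expect_equal(sc[["g2"]], 0)              # EOM gene at TA level
  expect_equal(ct[["g2"]], "responsive")
  expect_equal(sc[["g3"]], 50)             # midway -> intermediate
  expect_equal(ct[["g3"]], "intermediate")
  expect_equal(sc[["g4"]], -25)            # below m_EOM: negative, resistant
  expect_equal(ct[["g4"]], "resistant")
  expect_equal(sc[["g5"]], 25)             # boundary is intermediate
  expect_equal(ct[["g5"]], "intermediate")
  # zero denominator genes are skipped with a warning
  degs0 <- data.frame(gene_id = "g1", specificity = "TA")
  ee0 <- mk(eom_pre = 3, ta_pre = 3, eom_post = 3)
  expect_warning(out <- rescaleAndClassify(ee0, degs0), "equal")
  expect_equal(nrow(out), 0L)
})

test_that("plasticity fractions normalise within specificity", {
  calls <- data.frame(
    gene_id = sprintf("g%d", 1:10),
    specificity = rep(c("EOM", "TA"), c(4, 6)),
    rescaled_score = 0,
    category = c(rep("responsive", 4),
                 rep(c("responsive", "resistant"), 3)))
  fr <- plasticityFractions(calls)
  eom <- fr[fr$specificity == "EOM", ]
  expect_equal(eom$fraction[eom$category == "responsive"], 1)
  expect_equal(sum(eom$fraction), 1)
  expect_equal(sum(fr$fraction[fr$specificity == "TA"]), 1)
  expect_error(plasticityFractions(calls[0, ]), "no plasticity")
})

test_that("Hox expression profiles order by cluster and position", {
  sheet <- toySheet(3)
  genes <- data.frame(gene_id = c("b1", "a2", "a1"),
                      chrom = "chr5", strand = "+",
                      tss = c(9e6, 2e6, 1e6),
                      hox_cluster = c("HoxB", "HoxA", "HoxA"))
  counts <- matrix(rep(c(0L, 40L, 20L), 12), 3,
                   dimnames = list(genes$gene_id, sheet$sample_id))
  ee <- expressionExperiment(counts, sheet, genes)
  prof <- hoxExpressionProfile(ee)
  expect_equal(prof$gene_id, c("a1", "a2", "b1"))
  expect_equal(prof[prof$gene_id == "b1", "EOM-pre"], 0)
  expect_true(all(c("EOM-pre", "TA-post") %in% colnames(prof)))
})
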