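test_that("element methylation is the unweighted mean of site ratios", {
  el <- GRanges("chr1", IRanges(c(1000, 5000), width = 1000))
  names(el) <- c("e1", "e2")
  cs <- toyCalls(data.frame(chrom = "chr1",
                            pos = c(1100, 1200, 5100, 5200, 5300),
                            nMeth = c(1, 2, 2, 0, 4),
                            nUnmeth = c(4, 3, 2, 4, 0)))
  out <- elementMethylation(cs, el)
  # sites at 20% and 40% average to 30%
  expect_equal(out$meth[1], 30)
  # (2,2), (0,4), (4,0): mean(50, 0, 100) = 50
  expect_equal(out$meth[2], 50)
  # one covered site < min_cpgs = 2 -> missing
  one <- toyCalls(data.frame(chrom = "chr1", pos = 1100, nMeth = 3,
                             nUnmeth = 1))
  expect_true(is.na(elementMethylation(one, el)$meth[1]))
  # invariant to record order
  perm <- toyCalls(data.frame(chrom = "chr1",
                              pos = c(5300, 1200, 5100, 1100, 5200),
                              nMeth = c(4, 2, 2, 1, 0),
                              nUnmeth = c(0, 3, 2, 4, 4)))
  expect_equal(elementMethylation(perm, el)$meth, out$meth)
})

test_that("group support filter retains the hand-enumerated element set", {
  # 20 elements, 4 groups x 4 samples; elements k are quantified in
  # exactly k-1 samples of EOM-pre (k = 1..20 capped at 4) and in all
  # samples elsewhere: elements with >= 3 EOM-pre values must survive
  sheet <- toySheet(4)
  n_el <- 20
  meth <- matrix(50, n_el, nrow(sheet),
                 dimnames = list(sprintf("el%02d", 1:n_el), sheet$sample_id))
  eom_pre <- which(sampleGroups(sheet) == "EOM-pre")
  quantified <- pmin(seq_len(n_el) - 1L, 4L)
  for (k in seq_len(n_el))
    if (quantified[k] < 4L)
      meth[k, eom_pre[seq_len(4L - quantified[k])]] <- NA
  me <- MethylationExperiment(meth, sheet)
  kept <- rownames(groupSupportFilter(me, min_samples = 3,
                                      groups = c("EOM-pre", "TA-pre")))
  expect_identical(kept, sprintf("el%02d", 4:20))
  # boundary: exactly 3 of 4 satisfies "at least 3"
  expect_true("el04" %in% kept)
  expect_false("el03" %in% kept)
  # empty group set is the identity
  expect_identical(dim(groupSupportFilter(me, groups = character(0))),
                   dim(me))
  # a listed group smaller than min_samples is an error
  expect_error(groupSupportFilter(me, min_samples = 5,
                                  groups = "EOM-pre"), "only 4")
})

test_that("feature class summary reports genome and per-class means", {
  full <- toyCalls(data.frame(chrom = "chr1", pos = c(100, 200, 5100),
                              nMeth = c(3, 2, 4), nUnmeth = c(0, 0, 0)))
  classes <- list(promoter = GRanges("chr1", IRanges(50, 250)))
  out <- featureClassSummary(list(full), classes)
  expect_equal(out$summary$mean_meth, c(100, 100))
  # genome mean of two sites at 0% and 100% is 50%
  half <- toyCalls(data.frame(chrom = "chr1", pos = c(100, 200),
                              nMeth = c(0, 5), nUnmeth = c(5, 0)))
  out2 <- featureClassSummary(list(half), classes)
  expect_equal(out2$summary$mean_meth[out2$summary$class == "genome"], 50)
  expect_warning(featureClassSummary(list(half), list(cgi = GRanges())),
                 "empty")
})

test_that("rolling Z standardises against the local window", {
  sheet <- toySheet(3)
  n <- 60
  meth <- matrix(rep(seq(10, 69, length.out = n), nrow(sheet)), n,
                 dimnames = list(sprintf("e%02d", 1:n), sheet$sample_id))
  # identical groups: all diffs zero -> z = 0 everywhere, none significant
  me <- MethylationExperiment(meth, sheet)
  rz <- rollingZTest(me, "EOM-pre", "TA-pre", window = 20)
  expect_true(all(rz$z == 0))
  expect_false(any(rz$significant))
  # plant one outlying difference >> the local spread; with a window of
  # 21 elements the outlier's own contribution to the window sd caps |z|
  # near sqrt(window), so expect a large but bounded score
  eom <- sampleGroups(sheet) == "EOM-pre"
  meth2 <- meth + matrix(rnorm(length(meth), 0, 0.5), n)
  meth2[30, eom] <- meth2[30, eom] + 40
  me2 <- MethylationExperiment(pmin(meth2, 100), sheet)
  rz2 <- rollingZTest(me2, "EOM-pre", "TA-pre", window = 20)
  expect_true(abs(rz2$z[rz2$element_id == "e30"]) > 4)
  expect_true(rz2$significant[rz2$element_id == "e30"])
  # against a direct local mean/sd computation at the outlier's rank
  v2 <- methValues(me2)
  d2 <- rowMeans(v2[, eom]) - rowMeans(v2[, sampleGroups(sheet) == "TA-pre"])
  a2 <- (rowMeans(v2[, eom]) +
           rowMeans(v2[, sampleGroups(sheet) == "TA-pre"])) / 2
  r30 <- rank(a2)[30]
  w <- d2[order(a2)][max(1, r30 - 10):min(n, r30 + 10)]
  expect_equal(rz2$z[rz2$element_id == "e30"],
               unname((d2[30] - mean(w)) / sd(w)), tolerance = 1e-10)
  # a window covering all elements equals the global Z-score
  rzg <- rollingZTest(me2, "EOM-pre", "TA-pre", window = 2 * n)
  glab <- sampleGroups(sheet)
  v <- methValues(me2)
  d <- rowMeans(v[, glab == "EOM-pre"]) - rowMeans(v[, glab == "TA-pre"])
  zg <- (d - mean(d)) / sd(d)
  expect_equal(rz2g <- rzg$z[match(names(d), rzg$element_id)], unname(zg),
               tolerance = 1e-12)
  expect_error(rollingZTest(me2, "EOM-pre", "TA-pre", window = 5), "window")
})

test_that("rolling Z flags about alpha under an exchangeable null", {
  withr::local_seed(19)
  sheet <- toySheet(10)
  n <- 5000
  base <- pmin(pmax(rnorm(n, 30, 10), 5), 95)
  depth <- 50
  meth <- matrix(100 * rbinom(n * nrow(sheet), depth, rep(base, nrow(sheet))
                              / 100) / depth, n,
                 dimnames = list(sprintf("n%04d", 1:n), sheet$sample_id))
  me <- MethylationExperiment(meth, sheet)
  rz <- rollingZTest(me, "EOM-pre", "TA-pre")
  rate <- mean(rz$significant)
  expect_gt(rate, 0.025)
  expect_lt(rate, 0.075)
})

test_that("pooled calls sum counts per site", {
  a <- toyCalls(data.frame(chrom = "chr1", pos = c(100, 200),
                           nMeth = c(1, 2), nUnmeth = c(1, 0)), "a")
  b <- toyCalls(data.frame(chrom = c("chr1", "chr2"), pos = c(100, 300),
                           nMeth = c(3, 1), nUnmeth = c(1, 1)), "b")
  p <- poolCalls(list(a, b))
  gr <- cpgCalls(p)
  key <- paste(as.character(seqnames(gr)), start(gr))
  expect_setequal(key, c("chr1 100", "chr1 200", "chr2 300"))
  expect_equal(mcols(gr)$nMeth[key == "chr1 100"], 4L)
  expect_equal(mcols(gr)$nUnmeth[key == "chr1 100"], 2L)
})

test_that("DMR calling applies the consecutive-site rule", {
  mk <- function(pct, pos = seq_along(pct) * 100) {
    toyCalls(data.frame(chrom = "chr1", pos = pos, nMeth = pct,
                        nUnmeth = 100 - pct))
  }
  # 6 consecutive sites at +12 points -> one DMR of 6 sites
  a <- mk(rep(62, 6)); b <- mk(rep(50, 6))
  d <- callDmrs(a, b)
  expect_equal(length(d), 1L)
  expect_equal(mcols(d)$n_sites, 6L)
  expect_equal(mcols(d)$direction, "hyper_in_A")
  expect_equal(mcols(d)$mean_diff, 12)
  # 4 qualifying sites are below min_sites
  expect_equal(length(callDmrs(mk(rep(62, 4)), mk(rep(50, 4)))), 0L)
  # a sub-threshold middle site splits 7 into runs of 3 and 3
  a7 <- mk(c(62, 62, 62, 52, 62, 62, 62)); b7 <- mk(rep(50, 7))
  expect_equal(length(callDmrs(a7, b7)), 0L)
  # strict mode needs more than min_sites
  expect_equal(length(callDmrs(mk(rep(62, 5)), mk(rep(50, 5)))), 1L)
  expect_equal(length(callDmrs(mk(rep(62, 5)), mk(rep(50, 5)),
                               strict = TRUE)), 0L)
})

test_that("DMR caller matches brute-force enumeration on random landscapes", {
  withr::local_seed(23)
  for (rep in 1:50) {
    n <- 120
    chrom <- sort(sample(c("chr1", "chr2"), n, replace = TRUE))
    pos <- unlist(lapply(split(seq_len(n), chrom), function(i)
      sort(sample.int(5000, length(i)))))
    depth <- 40
    pa <- 100 * rbinom(n, depth, 0.5) / depth
    pb <- 100 * rbinom(n, depth, 0.5) / depth
    a <- toyCalls(data.frame(chrom = chrom, pos = pos,
                             nMeth = round(pa * depth / 100),
                             nUnmeth = depth - round(pa * depth / 100)), "a")
    b <- toyCalls(data.frame(chrom = chrom, pos = pos,
                             nMeth = round(pb * depth / 100),
                             nUnmeth = depth - round(pb * depth / 100)), "b")
    got <- callDmrs(a, b, min_sites = 3)
    want <- bruteForceDmrs(chrom, pos, siteRatios(a)[match(paste(chrom, pos),
        paste(as.character(seqnames(cpgCalls(a))), start(cpgCalls(a))))],
      siteRatios(b)[match(paste(chrom, pos),
        paste(as.character(seqnames(cpgCalls(b))), start(cpgCalls(b))))],
      min_sites = 3)
    if (is.null(want)) {
      expect_equal(length(got), 0L)
    } else {
      df <- as.data.frame(got)
      expect_equal(nrow(df), nrow(want))
      expect_equal(df$start, want$start)
      expect_equal(df$end, want$end)
      expect_equal(mcols(got)$n_sites, want$n_sites)
      expect_equal(mcols(got)$mean_diff, want$mean_diff)
    }
  }
})

test_that("methylation correction equalises TA-post and TA-pre means", {
  withr::local_seed(31)
  sheet <- toySheet(4)
  n <- 50
  meth <- matrix(runif(n * nrow(sheet), 20, 80), n,
                 dimnames = list(sprintf("m%02d", 1:n), sheet$sample_id))
  post <- sheet$graft == "post"
  meth[, post] <- pmin(meth[, post] + 2.6, 100)  # a global graft gain
  me <- MethylationExperiment(meth, sheet)
  corr <- correctMethylation(me, clamp = FALSE)
  v <- methValues(corr)
  glab <- sampleGroups(sheet)
  expect_equal(rowMeans(v[, glab == "TA-post"]),
               rowMeans(v[, glab == "TA-pre"]), tolerance = 1e-12)
  # pre-graft values untouched
  expect_identical(v[, !post], meth[, !post])
  # clamping keeps the percentage range
  low <- meth; low[1, post] <- 1
  me2 <- MethylationExperiment(low, sheet)
  v2 <- methValues(correctMethylation(me2))
  expect_true(all(v2 >= 0 & v2 <= 100, na.rm = TRUE))
})

test_that("density shift test is seeded and detects planted shifts", {
  withr::local_seed(37)
  sheet <- toySheet(5)
  n <- 800
  meth <- matrix(rnorm(n * nrow(sheet), 40, 3), n,
                 dimnames = list(sprintf("d%03d", 1:n), sheet$sample_id))
  eom_pre <- sampleGroups(sheet) == "EOM-pre"
  target <- sprintf("d%03d", 1:120)
  meth[1:120, eom_pre] <- meth[1:120, eom_pre] + 10
  me <- MethylationExperiment(pmin(meth, 100), sheet)
  bg <- rownames(meth)
  r1 <- densityShiftTest(me, target, bg, "EOM-pre", "TA-pre",
                         n_background = 350, seed = 5)
  r2 <- densityShiftTest(me, target, bg, "EOM-pre", "TA-pre",
                         n_background = 350, seed = 5)
  expect_identical(r1, r2)  # same seed, same subset, same p
  expect_lt(r1$p, 0.05)
  expect_gt(r1$mean_shift, 5)
  expect_equal(r1$n_background, 350L)
  expect_error(densityShiftTest(me, target[1:2], bg, "EOM-pre", "TA-pre"),
               "fewer than 3")
})

test_that("Hox methylation profiles pool counts per group", {
  w <- GRanges("chr5", IRanges(c(1, 1001, 2001), width = 1000))
  names(w) <- c("w1", "w2", "w3")
  g1 <- toyCalls(data.frame(chrom = "chr5", pos = c(100, 1100),
                            nMeth = c(4, 4), nUnmeth = c(1, 1)), "x1")
  g2 <- toyCalls(data.frame(chrom = "chr5", pos = c(100, 1100),
                            nMeth = c(4, 4), nUnmeth = c(1, 1)), "x2")
  prof <- hoxMethylationProfile(list(A = list(g1), B = list(g2)), w)
  expect_equal(unname(prof["w1", ]), c(80, 80))
  expect_true(all(is.na(prof["w3", ])))  # empty window is missing
})
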