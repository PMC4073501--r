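test_that("probe layouts tile chromosomes at the requested spacing", {
  g <- genomeLayout("chr1", 1e6)
  pr <- makeProbes(g, meanSpacing = 3364, probeLen = 60, seed = 11)
  n <- length(pr)
  expect_gt(n, floor(1e6 / 3364) * 0.85)
  expect_lt(n, floor(1e6 / 3364) * 1.15)
  st <- GenomicRanges::start(pr)
  expect_true(all(diff(st) > 0))
  expect_true(all(st[-1] > GenomicRanges::end(pr)[-n]))  # non-overlapping
  realized <- (st[n] - st[1]) / (n - 1)
  expect_lt(abs(realized - 3364) / 3364, 0.05)
  expect_identical(pr, makeProbes(g, meanSpacing = 3364, probeLen = 60,
                                  seed = 11))
})

test_that("mitochondrial contig always carries exactly five probes", {
  g <- defaultGenome()
  pr <- makeProbes(g, seed = 3)
  expect_identical(sum(GenomicRanges::seqnames(pr) == "chrM"), 5L)
  pr2 <- makeProbes(g, meanSpacing = 50000, seed = 3)
  expect_identical(sum(GenomicRanges::seqnames(pr2) == "chrM"), 5L)
})

test_that("a chromosome shorter than one probe is rejected", {
  g <- genomeLayout(c("chr1", "tiny"), c(1e5, 40))
  expect_error(makeProbes(g, probeLen = 60), "shorter than one probe")
  expect_error(makeProbes(genomeLayout("chr1", 1e5), meanSpacing = 50,
                          probeLen = 60), "exceed")
})

test_that("planted events respect scope semantics and never overlap", {
  g <- defaultGenome()
  grp <- c(a1 = "taurine", a2 = "taurine", y1 = "yak", y2 = "yak")
  empty <- plantEvents(g, grp, eventDesign(0, 0, 0), seed = 1)
  expect_identical(nrow(empty), 0L)

  des <- eventDesign(nShared = 0, nGroup = 1, nPrivate = 0)
  tr <- plantEvents(g, grp, des, seed = 2)
  yak <- tr[tr$group == "yak", ]
  expect_identical(nrow(yak), 2L)
  expect_identical(yak$start[1], yak$start[2])
  expect_identical(yak$end[1], yak$end[2])
  expect_setequal(yak$sample, c("y1", "y2"))

  # stress the collision resolver: many events, then verify per-sample
  # non-overlap with an interval oracle
  for (seed in 1:5) {
    tr <- plantEvents(g, grp, eventDesign(4, 3, 3), seed = seed)
    for (s in unique(tr$sample)) {
      ev <- tr[tr$sample == s, ]
      for (i in seq_len(nrow(ev))) for (j in seq_len(nrow(ev))) {
        if (i < j && ev$chrom[i] == ev$chrom[j])
          expect_false(ev$start[i] <= ev$end[j] &&
                         ev$end[i] >= ev$start[j])
      }
    }
    sh <- tr[tr$scope == "shared-all", ]
    for (k in unique(paste(sh$chrom, sh$start)))
      expect_identical(sum(paste(sh$chrom, sh$start) == k), length(grp))
  }
  expect_error(plantEvents(g, grp, eventDesign(1, 0, 0,
                                               lenRange = c(2e7, 3e7))),
               "chromosome")
})

test_that("noiseless ratios equal log2(CN/2) with the CN=0 floor", {
  g <- genomeLayout("chr1", 2e5)
  pr <- makeProbes(g, meanSpacing = 2000, probeLen = 60, seed = 1)
  grp <- c(s1 = "g1")
  mkTruth <- function(cn) data.frame(
    sample = "s1", group = "g1", chrom = "chr1", start = 1, end = 2e5,
    cn = cn, scope = "private", stringsAsFactors = FALSE)
  for (cn in c(0L, 1L, 3L, 4L)) {
    x <- simulateRatios(pr, mkTruth(cn), grp, noiseSd = 0, seed = 1)
    expected <- if (cn == 0) -3 else log2(cn / 2)
    expect_equal(unname(log2Ratios(x)[, "s1"]),
                 rep(expected, length(pr)))
  }
  bg <- simulateRatios(pr, mkTruth(1)[0, ], grp, noiseSd = 0, seed = 1)
  expect_equal(unname(log2Ratios(bg)[, "s1"]), rep(0, length(pr)))
  expect_error(simulateRatios(pr, mkTruth(1), grp, noiseSd = -1), "noiseSd")
})

test_that("feature intervals carry the six QTL trait classes", {
  g <- defaultGenome()
  fx <- makeFeatures(g, nGenes = 40, nQtls = 60, seed = 5)
  expect_identical(sum(fx$kind == "gene"), 40L)
  expect_identical(sum(fx$kind == "QTL"), 60L)
  expect_true(all(fx$class[fx$kind == "QTL"] %in%
                    c("exterior", "health", "meat-carcass", "milk",
                      "production", "reproduction")))
  expect_true(all(is.na(fx$class[fx$kind == "gene"])))
  expect_identical(fx, makeFeatures(g, nGenes = 40, nQtls = 60, seed = 5))
  expect_identical(length(makeFeatures(g, 0, 0, seed = 1)), 0L)
})

test_that("phenotypes follow the additive model exactly when noiseless", {
  recs <- expand.grid(farm = c("f1", "f2"), breed = c("b1", "b2"),
                      genotype = c("gain", "loss", "normal"),
                      stringsAsFactors = FALSE)
  recs$sample <- paste0("s", seq_len(nrow(recs)))
  zero <- list(t1 = list(mu = 10, sd = 0,
                         farm = c(f1 = 0, f2 = 0), breed = c(b1 = 0, b2 = 0),
                         genotype = c(gain = 0, loss = 0, normal = 0)))
  ph <- simulatePhenotypes(recs, zero, seed = 1)
  expect_equal(ph$t1, rep(10, nrow(recs)))

  spec <- zero
  spec$t1$genotype <- c(gain = 0, loss = 5, normal = 0)
  spec$t1$farm <- c(f1 = 1, f2 = -1)
  ph <- simulatePhenotypes(recs, spec, seed = 1)
  expect_equal(ph$t1, 10 + spec$t1$farm[recs$farm] +
                 spec$t1$genotype[recs$genotype], ignore_attr = TRUE)

  bad <- recs; bad$farm[1] <- "f9"
  expect_error(simulatePhenotypes(bad, zero), "unknown farm")
})

test_that("noisy phenotype cell means obey the law-of-large-numbers bound", {
  n <- 200
  recs <- data.frame(sample = paste0("s", 1:(3 * n)),
                     farm = "f1", breed = "b1",
                     genotype = rep(c("gain", "loss", "normal"), each = n),
                     stringsAsFactors = FALSE)
  spec <- list(t1 = list(mu = 100, sd = 4, farm = c(f1 = 0),
                         breed = c(b1 = 0),
                         genotype = c(gain = -5, loss = 5, normal = 0)))
  ph <- simulatePhenotypes(recs, spec, seed = 42)
  for (gt in c("gain", "loss", "normal")) {
    expect_lt(abs(mean(ph$t1[ph$genotype == gt]) -
                    (100 + spec$t1$genotype[[gt]])),
              3 * 4 / sqrt(n))
  }
})

test_that("simulated Ct values encode copy number one cycle per doubling", {
  cn <- c(ref = 2L, s2 = 2L, s4 = 4L, s1 = 1L, s0 = 0L)
  w <- simulateQpcr(cn, "ref", baseCt = 25, controlCt = 20, repSd = 0,
                    seed = 1)
  ctOf <- function(s, a) mean(w$ct[w$sample == s & w$assay == a])
  expect_equal(ctOf("s2", "target"), 25)
  expect_equal(ctOf("s4", "target"), 24)
  expect_equal(ctOf("s1", "target"), 26)
  expect_equal(ctOf("s0", "target"), 40)  # no-amplification ceiling
  expect_equal(ctOf("s4", "BTF3"), 20)
  est <- relativeCopyNumber(w, "ref", "BTF3")
  expect_equal(est$rcn[est$sample == "s1"], 0.5)
  expect_error(simulateQpcr(c(a = 1L), "a"), "calibrator")
  expect_error(simulateQpcr(cn, "ref", nReps = 0), "nReps")
})
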