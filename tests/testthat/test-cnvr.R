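test_that("basic CNVR aggregation follows the overlap-union definition", {
  one <- buildCnvrs(makeCalls("chr1", 100, 200, "sA", "loss"),
                    c("sA", "sB", "sC", "sD"), "g")
  expect_identical(length(one), 1L)
  r <- regions(one)
  expect_identical(GenomicRanges::start(r), 100L)
  expect_identical(GenomicRanges::end(r), 200L)
  expect_equal(r$frequency, 1 / 4)

  both <- buildCnvrs(makeCalls("chr1", c(100, 150), c(200, 250),
                               c("sA", "sB"), c("gain", "loss")),
                     c("sA", "sB"), "g")
  r <- regions(both)
  expect_identical(length(both), 1L)
  expect_identical(c(GenomicRanges::start(r), GenomicRanges::end(r)),
                   c(100L, 250L))
  expect_identical(r$state, "both")
  expect_identical(carriers(both)[[1]], c("sA", "sB"))

  two <- buildCnvrs(makeCalls("chr1", c(1, 201), c(100, 300),
                              c("sA", "sA"), c("loss", "loss")),
                    "sA", "g")
  expect_identical(length(two), 2L)
  expect_error(buildCnvrs(makeCalls("chr1", 1, 5, "sZ", "loss"),
                          c("sA"), "g"), "outside the group")
})

test_that("bookended intervals (end == next start under half-open) stay apart", {
  # disk coordinates [0,100) and [100,200) are 1..100 and 101..200 here
  calls <- makeCalls("chr1", c(1, 101), c(100, 200), c("sA", "sB"),
                     c("loss", "loss"))
  expect_identical(length(buildCnvrs(calls, c("sA", "sB"), "g")), 2L)
})

test_that("CNVR components equal the brute-force overlap closure", {
  set.seed(55)
  for (rep in 1:50) {
    n <- sample(2:30, 1)
    df <- data.frame(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = sample(1:500, n, replace = TRUE))
    df$end <- df$start + sample(10:120, n, replace = TRUE)
    calls <- makeCalls(df$chrom, df$start, df$end,
                       sample(paste0("s", 1:6), n, replace = TRUE),
                       sample(c("gain", "loss"), n, replace = TRUE))
    got <- regions(buildCnvrs(calls, paste0("s", 1:6), "g"))
    want <- bruteForceClosure(df)
    expect_identical(length(got), nrow(want))
    ord <- order(as.character(GenomicRanges::seqnames(got)),
                 GenomicRanges::start(got))
    expect_identical(GenomicRanges::start(got)[ord], as.integer(want$start))
    expect_identical(GenomicRanges::end(got)[ord], as.integer(want$end))
    # every input call contained in exactly one CNVR
    hits <- GenomicRanges::findOverlaps(calls, got)
    expect_identical(S4Vectors::queryHits(hits), seq_along(calls))
    # pairwise disjoint
    expect_identical(
      length(GenomicRanges::findOverlaps(got, drop.self = TRUE)), 0L)
  }
})

test_that("aggregation is idempotent and order/relabelling invariant", {
  set.seed(9)
  n <- 20
  calls <- makeCalls(sample(c("chr1", "chr2"), n, TRUE),
                     st <- sample(1:400, n, TRUE), st + 50,
                     sample(c("sA", "sB", "sC"), n, TRUE),
                     sample(c("gain", "loss"), n, TRUE))
  cs <- buildCnvrs(calls, c("sA", "sB", "sC"), "g")
  # feed the CNVRs back as calls
  r <- regions(cs)
  refeed <- makeCalls(as.character(GenomicRanges::seqnames(r)),
                      GenomicRanges::start(r), GenomicRanges::end(r),
                      rep("sA", length(r)),
                      ifelse(r$state == "both", "loss", r$state))
  again <- regions(buildCnvrs(refeed, "sA", "g"))
  expect_identical(GenomicRanges::start(again), GenomicRanges::start(r))
  expect_identical(GenomicRanges::end(again), GenomicRanges::end(r))
  # input order
  perm <- sample(length(calls))
  cs2 <- buildCnvrs(calls[perm], c("sA", "sB", "sC"), "g")
  expect_identical(as.data.frame(regions(cs2)), as.data.frame(regions(cs)))
  expect_identical(carriers(cs2), carriers(cs))
})

test_that("cross-group merging tracks provenance like the overlap oracle", {
  mk <- function(starts, ends, states, group, n)
    buildCnvrs(makeCalls("chr1", starts, ends,
                         rep(paste0(group, "_s1"), length(starts)), states),
               paste0(group, "_s", seq_len(n)), group)
  tau <- mk(c(100, 500), c(200, 600), c("loss", "gain"), "taurine", 4)
  yak <- mk(100, 200, "loss", "yak", 2)
  buf <- mk(800, 900, "gain", "buffalo", 2)
  merged <- mergeGroups(list(taurine = tau, yak = yak, buffalo = buf))
  expect_identical(length(merged), 3L)
  r <- regions(merged)
  expect_setequal(r$groups, c("taurine,yak", "taurine", "buffalo"))
  vc <- vennCounts(merged)
  expect_identical(vc[["taurine,yak"]], 1L)
  expect_identical(attr(vc, "per_group")[["taurine"]], 2L)
  expect_equal(sum(groupSizes(merged)), 8)

  # three disjoint group-exclusive regions -> three singleton provenances
  m2 <- mergeGroups(list(
    taurine = mk(1, 50, "loss", "taurine", 2),
    yak = mk(100, 150, "loss", "yak", 2),
    buffalo = mk(200, 250, "loss", "buffalo", 2)))
  expect_identical(length(m2), 3L)
  expect_true(all(!grepl(",", regions(m2)$groups)))

  # nested overlap chains across groups collapse transitively
  set.seed(31)
  for (rep in 1:20) {
    sets <- list()
    df <- NULL
    for (g in c("A", "B", "C")) {
      n <- sample(1:8, 1)
      st <- sample(1:300, n)
      cs <- buildCnvrs(makeCalls("chr1", st, st + sample(20:80, n, TRUE),
                                 rep(paste0(g, "1"), n),
                                 rep("loss", n)),
                       paste0(g, "1"), g)
      sets[[g]] <- cs
      r <- regions(cs)
      df <- rbind(df, data.frame(chrom = "chr1",
                                 start = GenomicRanges::start(r),
                                 end = GenomicRanges::end(r),
                                 group = g))
    }
    got <- regions(mergeGroups(sets))
    want <- bruteForceClosure(df)
    expect_identical(GenomicRanges::start(got), as.integer(want$start))
    expect_identical(GenomicRanges::end(got), as.integer(want$end))
    wantProv <- vapply(want$members, function(ix)
      paste(intersect(c("A", "B", "C"), unique(df$group[ix])),
            collapse = ","), "")
    expect_identical(got$groups, wantProv)
  }
})

test_that("the summary table reproduces printed-count arithmetic", {
  # a CNVR set realising 113 gain + 329 loss + 44 both totalling 71.5 Mb
  # on a 2,918.1 Mb assembly
  n <- 486
  states <- rep(c("gain", "loss", "both"), c(113, 329, 44))
  lens <- rep(71.5e6 / n, n)
  starts <- cumsum(c(1, lens[-n] + 1))
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(starts, width = lens))
  gr$cnvr_id <- paste0("CNVR", 1:n)
  gr$state <- states
  gr$n_carriers <- rep(c(1L, 2L), c(96, n - 96))
  gr$frequency <- gr$n_carriers / 24
  gr$groups <- "taurine"
  cs <- CnvrSet(gr, lapply(gr$n_carriers, function(k) paste0("s", 1:k)),
                c(taurine = 24L))
  s <- summarizeCnvrs(cs, genomeLayout("chr1", 2918.1e6))
  expect_identical(s$cnvrs, 486L)
  expect_identical(s$gain + s$loss + s$both, s$cnvrs)
  expect_identical(s$unique, 96L)
  expect_equal(s$avg, 486 / 24, tolerance = 1e-12)
  expect_equal(round(s$pct_genome, 2), 2.45)
  expect_error(summarizeCnvrs(cs, genomeLayout("chr1", 1)[0, ]), "genome")
})

test_that("empty CNVR sets summarise to zero", {
  empty <- CnvrSet(
    GenomicRanges::GRanges(cnvr_id = character(0), state = character(0),
                           n_carriers = integer(0), frequency = numeric(0),
                           groups = character(0)),
    list(), c(g = 3L))
  s <- summarizeCnvrs(empty, defaultGenome())
  expect_identical(s$cnvrs, 0L)
  expect_equal(s$total_bp, 0)
  expect_equal(s$pct_genome, 0)
})

test_that("per-chromosome coverage conserves total CNVR length", {
  g <- genomeLayout(c("chr1", "chr2"), c(1000, 2000))
  gr <- GenomicRanges::GRanges(c("chr1", "chr2"),
                               IRanges::IRanges(c(1, 1), c(100, 2000)))
  gr$cnvr_id <- c("a", "b"); gr$state <- "loss"
  gr$n_carriers <- 1L; gr$frequency <- 0.5; gr$groups <- "g"
  cs <- CnvrSet(gr, list("s1", "s1"), c(g = 2L))
  cov <- chromCoverage(cs, g)
  expect_equal(cov$pct[cov$chrom == "chr1"], 10)
  expect_equal(cov$pct[cov$chrom == "chr2"], 100)
  expect_identical(cov$chrom[1], "chr2")  # ranked by coverage
  expect_equal(sum(cov$covered_bp), sum(IRanges::width(regions(cs))))
})
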